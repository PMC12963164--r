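test_that("expansion by factor 1 is the identity", {
  box <- bounding_box(100, 100, 200, 100)
  out <- expand_box(box, 1.0, frame_dims = c(1280, 720))
  expect_equal(unclass(out), unclass(box))
})

test_that("area-mode expansion scales each dimension by sqrt(factor)", {
  box <- bounding_box(100, 100, 200, 100)
  out <- expand_box(box, 1.2, frame_dims = c(1280, 720))
  s <- sqrt(1.2)
  # one pixel of rounding allowed per edge
  expect_lte(abs(out$w - 200 * s), 1)
  expect_lte(abs(out$h - 100 * s), 1)
  ratio <- (out$w * out$h) / (200 * 100)
  max_ratio <- ((200 * s + 2) * (100 * s + 2)) / (200 * 100)
  expect_gte(ratio, 1.2)
  expect_lte(ratio, max_ratio)
  # contains the input box
  expect_lte(out$x, box$x)
  expect_lte(out$y, box$y)
  expect_gte(out$x + out$w, box$x + box$w)
  expect_gte(out$y + out$h, box$y + box$h)
})

test_that("expansion clips at the frame edge but still contains the input", {
  frame_dims <- c(640, 360)
  box <- bounding_box(440, 100, 200, 100) # flush against the right edge
  out <- expand_box(box, 1.2, frame_dims = frame_dims)
  expect_gte(out$x, 0)
  expect_lte(out$x + out$w, frame_dims[1])
  expect_lte(out$x, box$x)
  expect_gte(out$x + out$w, box$x + box$w)
  expect_gte(out$y + out$h, box$y + box$h)
})

test_that("expansion is monotone in the factor", {
  set.seed(42)
  big <- c(100000, 100000)
  for (rep in 1:20) {
    box <- bounding_box(x = runif(1, 1000, 2000), y = runif(1, 1000, 2000),
                        w = runif(1, 50, 400), h = runif(1, 50, 400))
    factors <- sort(runif(3, 1, 3))
    boxes <- lapply(factors, function(f) expand_box(box, f, big))
    for (k in 1:2) {
      expect_lte(boxes[[k + 1]]$x, boxes[[k]]$x)
      expect_lte(boxes[[k + 1]]$y, boxes[[k]]$y)
      expect_gte(boxes[[k + 1]]$x + boxes[[k + 1]]$w,
                 boxes[[k]]$x + boxes[[k]]$w)
      expect_gte(boxes[[k + 1]]$y + boxes[[k + 1]]$h,
                 boxes[[k]]$y + boxes[[k]]$h)
    }
  }
  expect_error(expand_box(bounding_box(0, 0, 10, 10), 0.9, c(100, 100)),
               class = "drapewatch_config_error")
})

test_that("linear mode scales dimensions by the factor itself", {
  out <- expand_box(bounding_box(500, 500, 100, 50), 1.2, c(5000, 5000),
                    mode = "linear")
  expect_lte(abs(out$w - 120), 1)
  expect_lte(abs(out$h - 60), 1)
})

test_that("the built-in detector locates the bed before entry", {
  sc <- generate_scene(random_scene_config(31))
  box <- detect_bed(sc$video, sc$config$entry_time,
                    color_region_detector(sc$config$pre_drape_color))
  expect_gte(box_iou(box, sc$config$bed_box), 0.5)
  expect_equal(attr(box, "epoch"), 1L)
})

test_that("a detector that never fires exhausts floor(entry/60) epochs", {
  sc <- generate_scene(scene_config(duration = 400, entry_time = 185,
                                    drape_onset = 300, noise_sd = 0))
  calls <- 0
  never <- function(frame) {
    calls <<- calls + 1
    data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
               h = numeric(0), confidence = numeric(0))
  }
  expect_error(detect_bed(sc$video, 185, never),
               class = "bed_detection_failure")
  # epochs at entry-60, entry-120, entry-180; five frames each
  expect_equal(calls, 3 * 5)
})

test_that("retry falls back to an earlier epoch when the first fails", {
  sc <- generate_scene(random_scene_config(32, entry_time = 180))
  inner <- color_region_detector(sc$config$pre_drape_color)
  gated <- function(frame) {
    # refuse detections in the last pre-entry minute
    if (attr(frame, "dw_time") > 180 - 60 - 1e-9) {
      return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                        h = numeric(0), confidence = numeric(0)))
    }
    inner(frame)
  }
  video <- sc$video
  raw_frame <- video$frame
  video$frame <- function(i) {
    f <- raw_frame(i)
    attr(f, "dw_time") <- video$timestamps[i]
    f
  }
  box <- detect_bed(video, 180, gated)
  expect_equal(attr(box, "epoch"), 2L)
  expect_gte(box_iou(box, sc$config$bed_box), 0.5)
})

test_that("detection never inspects frames at or after patient entry", {
  sc <- generate_scene(random_scene_config(33, entry_time = 130))
  seen <- numeric(0)
  video <- sc$video
  raw_frame <- video$frame
  video$frame <- function(i) {
    seen <<- c(seen, video$timestamps[i])
    raw_frame(i)
  }
  detect_bed(video, 130, color_region_detector(sc$config$pre_drape_color))
  expect_true(all(seen < 130))
})

test_that("detection holds across 100 seeded unoccluded scenes", {
  ious <- vapply(1:100, function(s) {
    sc <- generate_scene(random_scene_config(4000 + s, duration = 130,
                                             drape_onset = 120,
                                             entry_time = 70))
    box <- detect_bed(sc$video, sc$config$entry_time,
                      color_region_detector(sc$config$pre_drape_color))
    box_iou(box, sc$config$bed_box)
  }, numeric(1))
  expect_equal(sum(ious >= 0.5), 100)
})
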