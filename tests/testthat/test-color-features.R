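test_that("sampling takes one frame every 30 at constant rate", {
  ts <- (0:299) / 30
  st <- sample_times(ts, entry_time = 0, end_time = 10)
  expect_equal(nrow(st), 10)
  expect_equal(st$frame, seq(1L, 271L, by = 30L)) # frames 0,30,...,270 (0-based)
  expect_equal(st$t, 0:9)
  expect_true(all(diff(st$frame) == 30))
})

test_that("an empty sampling interval yields no samples", {
  ts <- (0:299) / 30
  expect_equal(nrow(sample_times(ts, 5, 5)), 0)
  expect_error(sample_times(numeric(0), 0, 10), class = "drapewatch_input_error")
})

test_that("mean ROI color equals the per-pixel average", {
  # uniform ROI
  f <- array(rep(c(40, 120, 180), each = 50 * 60), dim = c(50, 60, 3))
  expect_equal(unname(mean_roi_color(f, bounding_box(10, 10, 20, 20))),
               c(40, 120, 180))
  # half black, half (200, 100, 50): rows 1:10 black within a 20-row box
  f2 <- array(0, dim = c(20, 10, 3))
  f2[11:20, , 1] <- 200
  f2[11:20, , 2] <- 100
  f2[11:20, , 3] <- 50
  expect_equal(unname(mean_roi_color(f2, bounding_box(0, 0, 10, 20))),
               c(100, 50, 25))
  # single-pixel ROI
  f3 <- array(runif(3 * 4 * 3, 0, 255), dim = c(3, 4, 3))
  expect_equal(unname(mean_roi_color(f3, bounding_box(2, 1, 1, 1))),
               c(f3[2, 3, 1], f3[2, 3, 2], f3[2, 3, 3]))
})

test_that("mean ROI color matches brute-force accumulation on random ROIs", {
  set.seed(77)
  for (rep in 1:100) {
    h <- sample(5:30, 1)
    w <- sample(5:30, 1)
    f <- array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
    bw <- sample(1:w, 1)
    bh <- sample(1:h, 1)
    bx <- sample(0:(w - bw), 1)
    by <- sample(0:(h - bh), 1)
    box <- bounding_box(bx, by, bw, bh)
    acc <- c(0, 0, 0)
    for (r in (by + 1):(by + bh)) {
      for (cc in (bx + 1):(bx + bw)) {
        acc <- acc + f[r, cc, ]
      }
    }
    expect_equal(unname(mean_roi_color(f, box)), acc / (bw * bh),
                 tolerance = 1e-12)
  }
})

test_that("a box clipped to zero area is an input error", {
  f <- array(0, dim = c(20, 20, 3))
  expect_error(mean_roi_color(f, bounding_box(25, 25, 5, 5)),
               class = "drapewatch_input_error")
})

test_that("cyan-like value follows its definition", {
  expect_equal(cyan_like(0, 255, 255), 255)
  for (v in c(0, 17, 128, 255)) expect_equal(cyan_like(v, v, v), 0)
  expect_equal(cyan_like(100, 200, 150), 75)
  expect_equal(cyan_like(180, 150, 130), -40)
  expect_error(cyan_like(-1, 0, 0), class = "drapewatch_input_error")
  expect_error(cyan_like(0, 300, 0), class = "drapewatch_input_error")
})

test_that("cyan-like value is linear in the color", {
  set.seed(5)
  for (rep in 1:50) {
    p <- runif(3, 0, 255)
    q <- runif(3, 0, 255)
    a <- runif(1)
    b <- 1 - a # convex combination stays in gamut
    mix <- a * p + b * q
    expect_equal(cyan_like(mix[1], mix[2], mix[3]),
                 a * cyan_like(p[1], p[2], p[3]) +
                   b * cyan_like(q[1], q[2], q[3]),
                 tolerance = 1e-10)
  }
})

test_that("entry normalization subtracts the baseline window mean", {
  # constant signal: all deltas zero
  const <- data.frame(t = 0:29, R = 100, G = 110, B = 120,
                      cyan = cyan_like(100, 110, 120))
  norm <- normalize_to_entry(const)
  expect_true(all(abs(c(norm$dR, norm$dG, norm$dB, norm$dCyan)) < 1e-12))

  # sheet color then drape color: dCyan = 110 - (-40) = 150
  samples <- data.frame(
    t = 0:39,
    R = c(rep(180, 20), rep(40, 20)),
    G = c(rep(150, 20), rep(120, 20)),
    B = c(rep(130, 20), rep(180, 20)))
  samples$cyan <- cyan_like(samples$R, samples$G, samples$B)
  norm2 <- normalize_to_entry(samples, baseline_window = 10)
  expect_equal(norm2$dCyan[40], 150)
  expect_equal(norm2$dR[40], -140)
  expect_true(all(abs(norm2$dCyan[norm2$t <= 10]) < 1e-12))

  expect_error(normalize_to_entry(data.frame(t = 50:60, R = 1, G = 1, B = 1,
                                             cyan = 0)),
               class = "drapewatch_input_error")
})

test_that("normalized trajectories are invariant to a constant color shift", {
  set.seed(9)
  base <- data.frame(t = 0:59, R = runif(60, 80, 120), G = runif(60, 80, 120),
                     B = runif(60, 80, 120))
  base$cyan <- cyan_like(base$R, base$G, base$B)
  shifted <- base
  shifted$R <- base$R + 30
  shifted$G <- base$G + 30
  shifted$B <- base$B + 30
  shifted$cyan <- cyan_like(shifted$R, shifted$G, shifted$B)
  a <- normalize_to_entry(base)
  b <- normalize_to_entry(shifted)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("dCyan rises monotonically through a noise-free drape ramp", {
  cfg <- scene_config(duration = 200, entry_time = 20, drape_onset = 100,
                      drape_ramp = 40, noise_sd = 0)
  sc <- generate_scene(cfg)
  feats <- extract_color_features(sc$video, cfg$bed_box, 20)
  norm <- normalize_to_entry(feats)
  ramp <- norm$dCyan[norm$t >= 80 & norm$t <= 120] # onset..onset+ramp rel. entry
  expect_true(all(diff(ramp) >= -1e-9))
  expect_gt(ramp[length(ramp)], 100)
})
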