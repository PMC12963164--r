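#' Configure a synthetic operating-room scene
#'
#' Builds the parameter set for [generate_scene()]. The scene emulates what a
#' ceiling surveillance camera sees around the operating bed: a static bed
#' region in `pre_drape_color` (sheet/skin tones, red-dominant), a patient
#' entry time, a draping onset after which a blue-dominant sterile drape
#' progressively covers the bed, optional transient staff occlusions, and the
#' two failure modes that force case exclusion in practice — transparent
#' drapes (the ROI color barely changes) and a static object blocking the bed
#' (the detector cannot find it).
#'
#' Drape placement is modeled as linear coverage growth: the covered fraction
#' of the ROI rises from 0 at `drape_onset` to 1 at `drape_onset +
#' drape_ramp`. A covered pixel shows
#' `(1 - transparency) * drape_color + transparency * underlying`, so
#' `transparency = 1` reproduces the transparent-drape exclusion. Occluders
#' are rectangles anchored at the left edge of the ROI covering the stated
#' fraction of its width for the stated time window.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param fps Nominal frames per second.
#' @param duration Scene length in seconds.
#' @param bed_box Ground-truth bed [bounding_box()]; must lie within the frame.
#' @param pre_drape_color,drape_color,background_color RGB triples in
#'   `[0, 255]`.
#' @param entry_time Patient entry, seconds from video start.
#' @param drape_onset Start of draping, seconds; must exceed `entry_time`.
#' @param drape_ramp Seconds over which drape coverage goes 0 to 1 (0 = step).
#' @param occlusions List of occlusion events, each
#'   `list(start =, end =, fraction =, color =)` with `fraction` the covered
#'   share of ROI width and `color` an RGB triple.
#' @param transparency Drape transparency in `[0, 1]`.
#' @param bed_occluder_present If `TRUE`, a static object in
#'   `bed_occluder_color` covers the bed for the whole video.
#' @param bed_occluder_color RGB triple of the static occluder.
#' @param noise_sd Per-channel Gaussian pixel noise standard deviation.
#' @param timestamp_jitter Half-width (seconds) of uniform jitter added to
#'   frame timestamps to emulate a variable frame rate; 0 keeps constant fps.
#' @param seed Integer seed; frames and annotation are reproducible for a
#'   fixed config + seed.
#' @param case_id,department,robot_assisted Annotation fields for the case.
#' @param incision_time Skin-incision time (seconds); defaults to
#'   `drape_onset + 462.6` (the typical draping-to-incision interval of about
#'   7.71 minutes), usually beyond the end of the video.
#' @return A `scene_config` object.
#' @seealso [generate_scene()], [scene_roi_mean()]
#' @export
scene_config <- function(frame_width = 640, frame_height = 360, fps = 30,
                         duration = 420,
                         bed_box = bounding_box(200, 120, 240, 140),
                         pre_drape_color = c(180, 150, 130),
                         drape_color = c(40, 120, 180),
                         background_color = c(70, 70, 75),
                         entry_time = 60, drape_onset = 300, drape_ramp = 15,
                         occlusions = list(), transparency = 0,
                         bed_occluder_present = FALSE,
                         bed_occluder_color = c(110, 110, 115),
                         noise_sd = 8, timestamp_jitter = 0, seed = 1L,
                         case_id = "case_001",
                         department = c("gastrointestinal", "hepatic"),
                         robot_assisted = FALSE,
                         incision_time = NULL) {
  department <- match.arg(department)
  cfg <- list(
    frame_width = as.integer(frame_width), frame_height = as.integer(frame_height),
    fps = fps, duration = duration, bed_box = bed_box,
    pre_drape_color = pre_drape_color, drape_color = drape_color,
    background_color = background_color,
    entry_time = entry_time, drape_onset = drape_onset, drape_ramp = drape_ramp,
    occlusions = occlusions, transparency = transparency,
    bed_occluder_present = isTRUE(bed_occluder_present),
    bed_occluder_color = bed_occluder_color,
    noise_sd = noise_sd, timestamp_jitter = timestamp_jitter,
    seed = as.integer(seed), case_id = case_id, department = department,
    robot_assisted = isTRUE(robot_assisted),
    incision_time = incision_time %||% (drape_onset + 462.6)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$frame_width < 1 || cfg$frame_height < 1 || cfg$fps <= 0 || cfg$duration <= 0) {
    stop_config("frame dimensions, fps and duration must be positive")
  }
  if (!(cfg$entry_time >= 0 && cfg$entry_time < cfg$drape_onset &&
        cfg$drape_onset < cfg$duration)) {
    stop_config("times must satisfy 0 <= entry_time < drape_onset < duration")
  }
  if (cfg$drape_ramp < 0) stop_config("drape_ramp must be >= 0")
  for (col in list(cfg$pre_drape_color, cfg$drape_color, cfg$background_color,
                   cfg$bed_occluder_color)) {
    if (!is_rgb(col)) stop_config("colors must be RGB triples in [0, 255]")
  }
  if (cfg$transparency < 0 || cfg$transparency > 1) {
    stop_config("transparency must lie in [0, 1]")
  }
  bb <- cfg$bed_box
  if (bb$x < 0 || bb$y < 0 || bb$x + bb$w > cfg$frame_width ||
      bb$y + bb$h > cfg$frame_height) {
    stop_config("bed_box must lie within the frame")
  }
  for (occ in cfg$occlusions) {
    if (!all(c("start", "end", "fraction", "color") %in% names(occ))) {
      stop_config("each occlusion needs start, end, fraction and color")
    }
    if (occ$start >= occ$end || occ$fraction < 0 || occ$fraction > 1 ||
        !is_rgb(occ$color)) {
      stop_config("invalid occlusion event")
    }
  }
  if (cfg$noise_sd < 0 || cfg$timestamp_jitter < 0) {
    stop_config("noise_sd and timestamp_jitter must be >= 0")
  }
  invisible(cfg)
}

# Drape coverage fraction of the ROI at time t (continuous, before row
# discretization).
drape_coverage <- function(cfg, t) {
  if (t < cfg$drape_onset) return(0)
  if (cfg$drape_ramp <= 0) return(1)
  min(1, (t - cfg$drape_onset) / cfg$drape_ramp)
}

# Per-pixel color of the drape over the bed, after alpha blending.
drape_pixel_color <- function(cfg) {
  (1 - cfg$transparency) * cfg$drape_color + cfg$transparency * cfg$pre_drape_color
}

render_frame <- function(cfg, t, noise_seed = NULL) {
  h <- cfg$frame_height
  w <- cfg$frame_width
  frame <- array(rep(cfg$background_color, each = h * w), dim = c(h, w, 3))
  rows <- box_rows(cfg$bed_box)
  cols <- box_cols(cfg$bed_box)
  for (ch in 1:3) frame[rows, cols, ch] <- cfg$pre_drape_color[ch]
  if (cfg$bed_occluder_present) {
    for (ch in 1:3) frame[rows, cols, ch] <- cfg$bed_occluder_color[ch]
  } else {
    cov <- drape_coverage(cfg, t)
    n_cov <- round(cov * length(rows))
    if (n_cov > 0) {
      dpc <- drape_pixel_color(cfg)
      for (ch in 1:3) frame[rows[seq_len(n_cov)], cols, ch] <- dpc[ch]
    }
  }
  for (occ in cfg$occlusions) {
    if (t >= occ$start && t < occ$end) {
      n_occ <- round(occ$fraction * length(cols))
      if (n_occ > 0) {
        for (ch in 1:3) frame[rows, cols[seq_len(n_occ)], ch] <- occ$color[ch]
      }
    }
  }
  if (cfg$noise_sd > 0) {
    frame <- with_seed(noise_seed, frame + stats::rnorm(length(frame), 0, cfg$noise_sd))
    frame[frame < 0] <- 0
    frame[frame > 255] <- 255
  }
  frame
}

#' Generate a synthetic operating-room scene
#'
#' Produces a lazily rendered frame sequence plus the ground-truth case
#' annotation. Frames are rendered on demand (`video$frame(i)`), each from a
#' deterministic per-frame sub-seed, so the whole video is bit-reproducible
#' for a fixed config without ever being held in memory.
#'
#' @param cfg A [scene_config()].
#' @return An object of class `or_scene` with elements:
#'   \describe{
#'     \item{video}{An `or_video`: `width`, `height`, `fps`, `timestamps`
#'       (seconds, one per frame) and `frame(i)`, returning frame `i`
#'       (1-based) as a `height x width x 3` array on a 0-255 scale, channels
#'       ordered R, G, B.}
#'     \item{annotation}{One-row data frame in the case-annotation schema
#'       (`case_id`, `department`, `robot_assisted`, `entry_s`, `handwash_s`,
#'       `sterilize_s`, `lamp_s`, `cradle_s`, `draping_s`, `incision_s`).}
#'     \item{config}{The input config (with ground-truth `bed_box`).}
#'   }
#' @examples
#' sc <- generate_scene(scene_config(duration = 120, entry_time = 10,
#'                                   drape_onset = 60, noise_sd = 0))
#' dim(sc$video$frame(1))
#' sc$annotation$draping_s
#' @export
generate_scene <- function(cfg) {
  validate_scene_config(cfg)
  n_frames <- floor(cfg$duration * cfg$fps)
  timestamps <- (seq_len(n_frames) - 1) / cfg$fps
  if (cfg$timestamp_jitter > 0) {
    jit <- with_seed(frame_seed(cfg$seed, 0),
                     stats::runif(n_frames, -cfg$timestamp_jitter, cfg$timestamp_jitter))
    timestamps <- sort(timestamps + jit)
  }
  video <- structure(list(
    width = cfg$frame_width, height = cfg$frame_height, fps = cfg$fps,
    timestamps = timestamps,
    frame = function(i) {
      if (i < 1 || i > n_frames) stop_input("frame index out of range")
      render_frame(cfg, timestamps[[i]], frame_seed(cfg$seed, i))
    }
  ), class = "or_video")

  # Plausible staff-action times for the single-scene annotation: actions sit
  # between entry and draping onset, incision a typical interval after onset.
  span <- cfg$drape_onset - cfg$entry_time
  annotation <- data.frame(
    case_id = cfg$case_id,
    department = cfg$department,
    robot_assisted = cfg$robot_assisted,
    entry_s = cfg$entry_time,
    handwash_s = cfg$entry_time + 0.35 * span,
    sterilize_s = cfg$entry_time + 0.55 * span,
    lamp_s = cfg$entry_time + 0.45 * span,
    cradle_s = cfg$entry_time + 0.40 * span,
    draping_s = cfg$drape_onset,
    incision_s = cfg$incision_time,
    stringsAsFactors = FALSE
  )
  structure(list(video = video, annotation = annotation, config = cfg),
            class = "or_scene")
}

#' @export
print.or_scene <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<or_scene %s: %dx%d @%g fps, %gs, entry %gs, draping %gs (ramp %gs)>\n",
    cfg$case_id, cfg$frame_width, cfg$frame_height, cfg$fps, cfg$duration,
    cfg$entry_time, cfg$drape_onset, cfg$drape_ramp))
  invisible(x)
}

#' Closed-form mean ROI color of a synthetic scene
#'
#' The noise-free mean color over the ground-truth bed box is a piecewise
#' function of time: background never enters the box, the drape covers
#' `round(c * h) / h` of the rows (the same row discretization the renderer
#' uses, with `c` the linear coverage fraction), and left-anchored occluders
#' overwrite their column span in list order. This closed form is what the
#' rendered frames must reproduce exactly at `noise_sd = 0`.
#'
#' @param cfg A [scene_config()].
#' @param t Time in seconds.
#' @return Named RGB vector of the exact ROI mean at time `t` (no noise).
#' @export
scene_roi_mean <- function(cfg, t) {
  h <- length(box_rows(cfg$bed_box))
  w <- length(box_cols(cfg$bed_box))
  if (cfg$bed_occluder_present) {
    base <- cfg$bed_occluder_color
    f_drape <- 0
    dpc <- cfg$bed_occluder_color
  } else {
    base <- cfg$pre_drape_color
    f_drape <- round(drape_coverage(cfg, t) * h) / h
    dpc <- drape_pixel_color(cfg)
  }
  col_mean <- f_drape * dpc + (1 - f_drape) * base

  # Left-anchored occluders drawn in list order: later ones overwrite earlier
  # ones, so column j shows the last active occluder whose span covers j.
  active <- Filter(function(o) t >= o$start && t < o$end, cfg$occlusions)
  spans <- vapply(active, function(o) round(o$fraction * w), numeric(1))
  covered <- 0
  mean_rgb <- col_mean * w
  if (length(active)) {
    for (k in rev(seq_along(active))) {
      extra <- max(0, spans[k] - covered)
      if (extra > 0) {
        mean_rgb <- mean_rgb + extra * (active[[k]]$color - col_mean)
        covered <- covered + extra
      }
    }
  }
  stats::setNames(mean_rgb / w, c("R", "G", "B"))
}

#' Draw a randomized scene configuration
#'
#' Varies bed placement/size, colors and draping times around realistic
#' defaults; used to exercise detection and the end-to-end pipeline across
#' many seeded scenes.
#'
#' @param seed Integer seed (also becomes the scene's frame seed).
#' @param ... Overrides passed on to [scene_config()] after randomization.
#' @return A `scene_config`.
#' @export
random_scene_config <- function(seed, ...) {
  with_seed(seed, {
    over <- list(...)
    fw <- over$frame_width %||% 640L
    fh <- over$frame_height %||% 360L
    duration <- over$duration %||% 420
    entry <- over$entry_time %||% 60
    w <- round(stats::runif(1, 180, 280))
    h <- round(stats::runif(1, 100, 160))
    x <- round(stats::runif(1, 40, fw - w - 40))
    y <- round(stats::runif(1, 40, fh - h - 40))
    onset <- round(entry + stats::runif(1, 0.35, 0.85) * (duration - entry - 30))
    pre <- round(c(stats::runif(1, 160, 200), stats::runif(1, 135, 165),
                   stats::runif(1, 115, 145)))
    drape <- round(c(stats::runif(1, 25, 60), stats::runif(1, 100, 140),
                     stats::runif(1, 160, 200)))
    args <- list(bed_box = bounding_box(x, y, w, h), drape_onset = onset,
                 pre_drape_color = pre, drape_color = drape, seed = seed,
                 case_id = sprintf("case_%04d", seed))
    args[names(over)] <- over
    do.call(scene_config, args)
  })
}

#' Look up the frame index at or immediately before a time
#'
#' @param video An `or_video`.
#' @param t Time in seconds.
#' @return 1-based frame index.
#' @export
frame_index_at <- function(video, t) {
  i <- findInterval(t, video$timestamps)
  if (i < 1) stop_input("requested time precedes the first frame")
  i
}

#' Write scene frames as PNG files
#'
#' Convenience export of selected frames (requires the `png` package).
#'
#' @param scene An `or_scene`.
#' @param dir Output directory (created if needed).
#' @param times Times (seconds) to export; nearest preceding frame is used.
#' @return Invisibly, the written file paths.
#' @export
write_scene_frames <- function(scene, dir, times) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write frames")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(times, function(t) {
    i <- frame_index_at(scene$video, t)
    f <- scene$video$frame(i) / 255
    path <- file.path(dir, sprintf("frame_t%07.2f.png", t))
    png::writePNG(f, path)
    path
  }, character(1))
  invisible(paths)
}
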