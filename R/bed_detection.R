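#' Built-in color-region bed detector for synthetic scenes
#'
#' Returns a detector function (the detector interface: `frame ->` data frame
#' of candidates `x, y, w, h, confidence`) that finds the axis-aligned extent
#' of pixels matching a reference bed color within a per-channel tolerance.
#' This is a stand-in detector for synthetic scenes built on the known bed
#' appearance; it is not a trained object-detection model, which is what a
#' production deployment would plug in through the same interface.
#'
#' Confidence is the fill ratio of matching pixels inside their bounding
#' extent, so a clean rectangular bed scores near 1.
#'
#' @param reference_rgb RGB triple of the (un-draped) bed appearance.
#' @param tol Per-channel absolute tolerance (0-255 scale).
#' @param min_pixels Minimum number of matching pixels; below this the
#'   detector reports no candidates.
#' @return A function `frame -> data.frame(x, y, w, h, confidence)`.
#' @export
color_region_detector <- function(reference_rgb = c(180, 150, 130), tol = 30,
                                  min_pixels = 400) {
  if (!is_rgb(reference_rgb)) stop_config("reference_rgb must be RGB in [0, 255]")
  function(frame) {
    mask <- abs(frame[, , 1] - reference_rgb[1]) <= tol &
      abs(frame[, , 2] - reference_rgb[2]) <= tol &
      abs(frame[, , 3] - reference_rgb[3]) <= tol
    n <- sum(mask)
    if (n < min_pixels) {
      return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                        h = numeric(0), confidence = numeric(0)))
    }
    idx <- which(mask, arr.ind = TRUE)
    r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
    c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
    area <- (r2 - r1 + 1) * (c2 - c1 + 1)
    data.frame(x = c1 - 1, y = r1 - 1, w = c2 - c1 + 1, h = r2 - r1 + 1,
               confidence = min(1, n / area))
  }
}

#' Retry policy for pre-entry bed detection
#'
#' @param interval Seconds between attempt epochs stepping backward from
#'   patient entry (default one minute).
#' @param frames_per_attempt Frames inspected per epoch (default five).
#' @param frame_spacing Seconds between those frames.
#' @return A `retry_config` list.
#' @export
retry_config <- function(interval = 60, frames_per_attempt = 5,
                         frame_spacing = 1) {
  if (interval <= 0 || frames_per_attempt < 1 || frame_spacing < 0) {
    stop_config("invalid retry configuration")
  }
  structure(list(interval = interval,
                 frames_per_attempt = as.integer(frames_per_attempt),
                 frame_spacing = frame_spacing),
            class = "retry_config")
}

#' Locate the operating bed before patient entry
#'
#' Detection is attempted one minute before the patient enters, on five
#' frames spaced one second apart; if no candidate is found the attempt is
#' repeated one minute earlier, and so on until the start of the video. The
#' highest-confidence candidate of the first epoch that yields any detection
#' is returned. When every epoch fails, a `bed_detection_failure` condition
#' is signalled; the pipeline reports such a case as a detection failure.
#' Frames at or after `entry_time` are never inspected.
#'
#' @param video An `or_video` (or any list with `timestamps` and `frame(i)`).
#' @param entry_time Patient entry, seconds; must be at least one retry
#'   interval into the video.
#' @param detector Detector function, e.g. [color_region_detector()].
#' @param retry A [retry_config()].
#' @return The winning `bounding_box`, with attributes `confidence` and
#'   `epoch` (1 = the attempt one minute before entry).
#' @export
detect_bed <- function(video, entry_time, detector, retry = retry_config()) {
  if (entry_time < retry$interval) {
    stop_config("entry_time must be at least one retry interval into the video")
  }
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    t0 <- entry_time - retry$interval * epoch
    if (t0 < video$timestamps[[1]]) {
      stop(errorCondition(
        sprintf("bed not detected in any of %d pre-entry attempts", epoch - 1L),
        class = c("bed_detection_failure", "error", "condition")))
    }
    best <- NULL
    for (j in seq_len(retry$frames_per_attempt) - 1L) {
      t <- t0 + j * retry$frame_spacing
      if (t >= entry_time) next
      cand <- detector(video$frame(frame_index_at(video, t)))
      if (nrow(cand) > 0) {
        top <- cand[which.max(cand$confidence), ]
        if (is.null(best) || top$confidence > best$confidence) best <- top
      }
    }
    if (!is.null(best)) {
      box <- bounding_box(best$x, best$y, best$w, best$h)
      attr(box, "confidence") <- best$confidence
      attr(box, "epoch") <- epoch
      return(box)
    }
  }
}
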