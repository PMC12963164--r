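#' Sample timestamps every 30 frames
#'
#' After patient entry the ROI color is evaluated every `stride` frames —
#' nearly once per second at a nominal 30 fps. Sampling is by frame stride,
#' as the acquisition pipeline works frame-wise, but timestamps are carried
#' along so downstream stages and evaluation operate in seconds even under a
#' variable frame rate.
#'
#' @param timestamps Frame timestamps in seconds (nondecreasing).
#' @param entry_time Patient entry, seconds.
#' @param end_time End of sampling (exclusive), seconds.
#' @param stride Frame stride between samples.
#' @return Data frame with `frame` (1-based frame index) and `t` (seconds).
#' @examples
#' ts <- (0:299) / 30
#' sample_times(ts, entry_time = 0, end_time = 10)
#' @export
sample_times <- function(timestamps, entry_time, end_time, stride = 30L) {
  if (length(timestamps) == 0) stop_input("empty timestamp list")
  if (entry_time >= end_time) {
    return(data.frame(frame = integer(0), t = numeric(0)))
  }
  i0 <- which(timestamps >= entry_time)
  if (length(i0) == 0) {
    return(data.frame(frame = integer(0), t = numeric(0)))
  }
  idx <- seq.int(i0[[1]], length(timestamps), by = stride)
  idx <- idx[timestamps[idx] < end_time]
  data.frame(frame = as.integer(idx), t = timestamps[idx])
}

#' Mean color of a region of interest
#'
#' Per-channel arithmetic mean over every pixel of the (clipped) box — the
#' deliberately "blurred" color summary the drape classifier runs on.
#'
#' @param frame `height x width x 3` array, channels R, G, B on 0-255 scale.
#' @param box A [bounding_box()]; clipped to the frame, must keep positive
#'   area.
#' @return Named numeric vector `c(R =, G =, B =)`.
#' @export
mean_roi_color <- function(frame, box) {
  d <- dim(frame)
  box <- clip_box(box, width = d[2], height = d[1])
  rows <- box_rows(box)
  cols <- box_cols(box)
  c(R = mean(frame[rows, cols, 1]),
    G = mean(frame[rows, cols, 2]),
    B = mean(frame[rows, cols, 3]))
}

#' Cyan-like value
#'
#' The custom scalar `(G + B) / 2 - R`: large when the ROI is dominated by
#' the blue-green of sterile drapes, zero for any gray, negative for
#' red-dominant sheet and skin tones. Not clamped; range `[-255, 255]` for
#' in-gamut inputs.
#'
#' @param r,g,b Channel means in `[0, 255]` (vectorized).
#' @return `(g + b) / 2 - r`.
#' @examples
#' cyan_like(0, 255, 255) # pure cyan: 255
#' cyan_like(128, 128, 128) # gray: 0
#' @export
cyan_like <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 255, na.rm = TRUE)) {
    stop_input("channel values must lie in [0, 255]")
  }
  (g + b) / 2 - r
}

#' Extract the ROI color time series of a case
#'
#' Samples the video every `stride` frames from patient entry, computing the
#' mean ROI color and the cyan-like value at each sample. Samples whose ROI
#' cannot be read (unreadable frame, non-finite pixels) are dropped with a
#' warning rather than interpolated.
#'
#' @param video An `or_video`.
#' @param box ROI [bounding_box()] (typically the expanded bed box).
#' @param entry_time Patient entry, seconds.
#' @param end_time End of sampling; defaults to the end of the video.
#' @param stride Frame stride between samples.
#' @return Data frame with `t` (seconds since entry), `t_video` (seconds on
#'   the video clock), `R`, `G`, `B`, `cyan`.
#' @export
extract_color_features <- function(video, box, entry_time, end_time = NULL,
                                   stride = 30L) {
  end_time <- end_time %||% (video$timestamps[[length(video$timestamps)]] +
                               1 / video$fps)
  st <- sample_times(video$timestamps, entry_time, end_time, stride)
  n <- nrow(st)
  out <- matrix(NA_real_, n, 3)
  ok <- logical(n)
  for (i in seq_len(n)) {
    rgb <- tryCatch(mean_roi_color(video$frame(st$frame[[i]]), box),
                    error = function(e) NULL)
    if (!is.null(rgb) && all(is.finite(rgb))) {
      out[i, ] <- rgb
      ok[i] <- TRUE
    }
  }
  if (any(!ok)) {
    warning(sprintf("dropped %d unreadable sample(s)", sum(!ok)))
  }
  data.frame(t = st$t[ok] - entry_time,
             t_video = st$t[ok],
             R = out[ok, 1], G = out[ok, 2], B = out[ok, 3],
             cyan = cyan_like(out[ok, 1], out[ok, 2], out[ok, 3]))
}

#' Normalize color features to patient entry
#'
#' Subtracts a per-feature baseline — the mean over the samples within
#' `baseline_window` seconds of entry — from each sample, yielding the
#' deltas the classifier consumes. Subtraction (not division) keeps the
#' additive structure of the color traces visible.
#'
#' @param samples Data frame from [extract_color_features()] (columns `t`,
#'   `R`, `G`, `B`, `cyan`).
#' @param baseline_window Length of the baseline window in seconds after
#'   entry (default 10, i.e. about the first ten 1 Hz samples).
#' @return Data frame with `t` (and `t_video` if present) plus `dR`, `dG`,
#'   `dB`, `dCyan`.
#' @export
normalize_to_entry <- function(samples, baseline_window = 10) {
  base_idx <- samples$t >= 0 & samples$t <= baseline_window
  if (!any(base_idx)) stop_input("no samples inside the baseline window")
  out <- data.frame(t = samples$t)
  if (!is.null(samples$t_video)) out$t_video <- samples$t_video
  out$dR <- samples$R - mean(samples$R[base_idx])
  out$dG <- samples$G - mean(samples$G[base_idx])
  out$dB <- samples$B - mean(samples$B[base_idx])
  out$dCyan <- samples$cyan - mean(samples$cyan[base_idx])
  out
}
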