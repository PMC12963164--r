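#' Confirm a draping event from a classification stream
#'
#' Scans the time-ordered per-sample labels for the first run of
#' `run_length` consecutive `"after"` classifications — at the nominal one
#' sample per second, ten consecutive positive seconds. Any `"before"`
#' sample resets the run (strict consecutiveness), which suppresses premature
#' triggers from isolated misclassifications. A missing-sample gap longer
#' than `max_gap` also resets the run, since consecutiveness in time can no
#' longer be vouched for; shorter gaps (the odd dropped frame) do not.
#'
#' @param stream Data frame with `t` (seconds, nondecreasing) and `label`
#'   (`"before"` / `"after"`); a `t_video` column, if present, is used to
#'   report times on the video clock as well.
#' @param run_length Required number of consecutive positive samples
#'   (default 10).
#' @param max_gap Largest inter-sample gap (seconds) that keeps a run alive;
#'   defaults to twice the median sample spacing.
#' @return A `draping_detection`: list with `status` (`"detected"` or
#'   `"not_detected"`), `onset_t` (time of the first sample of the confirming
#'   run), `confirm_t` (time of its `run_length`-th sample), both in the
#'   stream's time base (`NA` when not detected), and `run_length`.
#' @examples
#' s <- data.frame(t = 0:29, label = rep(c("before", "after"), c(15, 15)))
#' confirm_draping(s)
#' @export
confirm_draping <- function(stream, run_length = 10L, max_gap = NULL) {
  if (run_length < 1) stop_config("run_length must be >= 1")
  n <- nrow(stream)
  if (n == 0) {
    return(new_detection("not_detected", run_length = run_length))
  }
  t <- stream$t
  if (is.unsorted(t)) stop_input("classification stream must be time-ordered")
  lab <- as.character(stream$label)
  if (is.null(max_gap)) {
    max_gap <- if (n >= 2) 2 * stats::median(diff(t)) else Inf
  }
  count <- 0L
  start <- NA_integer_
  for (i in seq_len(n)) {
    if (identical(lab[[i]], "after")) {
      if (count > 0L && (t[[i]] - t[[i - 1L]]) > max_gap) count <- 0L
      if (count == 0L) start <- i
      count <- count + 1L
      if (count == run_length) {
        det <- new_detection("detected", onset_t = t[[start]],
                             confirm_t = t[[i]], run_length = run_length)
        if (!is.null(stream$t_video)) {
          det$onset_t_video <- stream$t_video[[start]]
          det$confirm_t_video <- stream$t_video[[i]]
        }
        return(det)
      }
    } else {
      count <- 0L
    }
  }
  new_detection("not_detected", run_length = run_length)
}

new_detection <- function(status, onset_t = NA_real_, confirm_t = NA_real_,
                          run_length = 10L, case_id = NA_character_) {
  structure(list(status = status, onset_t = onset_t, confirm_t = confirm_t,
                 run_length = as.integer(run_length), case_id = case_id),
            class = "draping_detection")
}

#' @export
print.draping_detection <- function(x, ...) {
  if (identical(x$status, "detected")) {
    clock <- if (!is.null(x$onset_s) && !is.na(x$onset_s)) {
      sprintf(" (video clock %.1f s)", x$onset_s)
    } else ""
    cat(sprintf(
      "<draping_detection %s: detected, onset %.1f s after entry%s, confirmed %.1f s>\n",
      x$case_id, x$onset_t, clock, x$confirm_t))
  } else {
    cat(sprintf("<draping_detection %s: %s>\n", x$case_id, x$status))
  }
  invisible(x)
}

#' Pipeline configuration for a single case
#'
#' @param expand_factor Bed-box expansion factor (default 1.2).
#' @param expand_mode `"area"` (default) or `"linear"`; see [expand_box()].
#' @param stride Frame stride between color samples (default 30).
#' @param baseline_window Entry-normalization window, seconds (default 10).
#' @param run_length Consecutive positive samples required to confirm
#'   (default 10).
#' @param end_time Stop sampling at this video time (default: video end).
#' @param report `"onset"` (default) reports the first sample of the
#'   confirming run as the event time; `"confirm"` reports its last.
#' @param retry Bed-detection [retry_config()].
#' @return A `case_config` list.
#' @export
case_config <- function(expand_factor = 1.2, expand_mode = "area",
                        stride = 30L, baseline_window = 10,
                        run_length = 10L, end_time = NULL,
                        report = c("onset", "confirm"),
                        retry = retry_config()) {
  structure(list(expand_factor = expand_factor, expand_mode = expand_mode,
                 stride = as.integer(stride),
                 baseline_window = baseline_window,
                 run_length = as.integer(run_length), end_time = end_time,
                 report = match.arg(report), retry = retry),
            class = "case_config")
}

#' Run the full draping-detection pipeline on one case
#'
#' Composes the three stages: (1) bed detection before patient entry with
#' the backward retry policy, and 1.2-fold expansion of the winning box;
#' (2) per-second mean-ROI-color sampling, cyan-like value and entry
#' normalization; (3) SVM classification and the consecutive-positive
#' confirmation rule. A bed-detection failure is caught and reported as
#' `status = "bed_detection_failed"`; a stream with no confirming run ends
#' as `"not_detected"`. One event at most is reported per case.
#'
#' @param x An `or_scene` (video, entry time and case id are taken from it)
#'   or an `or_video`.
#' @param model Classifier for [classify_samples()].
#' @param detector Detector function; defaults to the built-in
#'   [color_region_detector()].
#' @param config A [case_config()].
#' @param entry_time Patient entry (seconds); required when `x` is a bare
#'   video.
#' @param case_id Case identifier carried into the result.
#' @param keep_trace Attach the per-sample feature/classification trace.
#' @return A `draping_detection` with `status` in `"detected"`,
#'   `"not_detected"`, `"bed_detection_failed"`; for detections, `onset_t` /
#'   `confirm_t` (seconds since entry), `onset_s` / `confirm_s` (video
#'   clock) and the reported `event_s` per `config$report`; plus `bed_box`
#'   and, optionally, `trace`.
#' @export
run_case <- function(x, model, detector = NULL, config = case_config(),
                     entry_time = NULL, case_id = NULL, keep_trace = FALSE) {
  if (inherits(x, "or_scene")) {
    video <- x$video
    entry_time <- entry_time %||% x$config$entry_time
    case_id <- case_id %||% x$config$case_id
    detector <- detector %||% color_region_detector(x$config$pre_drape_color)
  } else {
    video <- x
    if (is.null(entry_time)) stop_input("entry_time is required for a bare video")
    detector <- detector %||% color_region_detector()
    case_id <- case_id %||% NA_character_
  }

  raw_box <- tryCatch(
    detect_bed(video, entry_time, detector, config$retry),
    bed_detection_failure = function(e) NULL
  )
  if (is.null(raw_box)) {
    det <- new_detection("bed_detection_failed", run_length = config$run_length,
                         case_id = case_id)
    det$event_s <- NA_real_
    return(det)
  }
  roi <- expand_box(raw_box, config$expand_factor,
                    frame_dims = c(video$width, video$height),
                    mode = config$expand_mode)

  feats <- extract_color_features(video, roi, entry_time,
                                  end_time = config$end_time,
                                  stride = config$stride)
  norm <- normalize_to_entry(feats, config$baseline_window)
  labels <- classify_samples(model, norm)
  stream <- data.frame(t = norm$t, t_video = norm$t_video, label = labels)
  det <- confirm_draping(stream, run_length = config$run_length)
  det$case_id <- case_id
  det$bed_box <- raw_box
  det$roi <- roi
  det$onset_s <- det$onset_t_video %||% NA_real_
  det$confirm_s <- det$confirm_t_video %||% NA_real_
  det$event_s <- if (identical(config$report, "confirm")) det$confirm_s else det$onset_s
  if (keep_trace) {
    trace <- cbind(feats, norm[c("dR", "dG", "dB", "dCyan")])
    trace$label <- labels
    det$trace <- trace
  }
  det
}
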