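#' Score detections against annotated draping onsets
#'
#' Computes, over the detected cases, the signed timing error
#' `detected - annotated` in seconds (negative = detection earlier than the
#' annotation) and summarizes it with median, quartiles (type-7, linear
#' interpolation), mean and standard deviation. Cases where the system could
#' not identify draping (no confirming run, or bed detection failed) are
#' excluded from the error statistics and counted in the detection rate
#' instead.
#'
#' @param detections List of `draping_detection` objects (with `case_id` and
#'   `event_s`) or a data frame with columns `case_id`, `status`, `event_s`.
#' @param annotations Annotation table containing the same `case_id`s.
#' @param tolerances Tolerances (seconds) for which the fraction of detected
#'   cases with `|error| <= tol` is reported; default ±120 s.
#' @return An `error_summary`: `n_cases`, `n_detected`, `detection_rate`,
#'   `errors` (named by case), `median`, `q1`, `q3`, `mean`, `sd`,
#'   `fraction_within`.
#' @export
score_detections <- function(detections, annotations, tolerances = 120) {
  if (!is.data.frame(detections)) {
    detections <- do.call(rbind, lapply(detections, function(d) {
      data.frame(case_id = d$case_id, status = d$status,
                 event_s = d$event_s %||% NA_real_, stringsAsFactors = FALSE)
    }))
  }
  miss <- setdiff(detections$case_id, annotations$case_id)
  if (length(miss)) {
    stop_input(paste("no annotation for case(s):", paste(miss, collapse = ", ")))
  }
  ann <- annotations[match(detections$case_id, annotations$case_id), ]
  detected <- detections$status == "detected"
  errors <- detections$event_s[detected] - ann$draping_s[detected]
  names(errors) <- detections$case_id[detected]
  n_det <- sum(detected)
  qs <- if (n_det > 0) stats::quantile(errors, c(0.25, 0.5, 0.75), type = 7,
                                       names = FALSE) else rep(NA_real_, 3)
  structure(list(
    n_cases = nrow(detections),
    n_detected = n_det,
    detection_rate = n_det / nrow(detections),
    errors = errors,
    median = qs[2], q1 = qs[1], q3 = qs[3],
    mean = if (n_det > 0) mean(errors) else NA_real_,
    sd = if (n_det > 1) stats::sd(errors) else if (n_det == 1) 0 else NA_real_,
    sd_degenerate = n_det < 2,
    fraction_within = stats::setNames(
      vapply(tolerances, function(tol) {
        if (n_det == 0) NA_real_ else mean(abs(errors) <= tol)
      }, numeric(1)),
      paste0("within_", tolerances, "s"))
  ), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("Detection: %d/%d cases (%.1f%%)\n", x$n_detected, x$n_cases,
              100 * x$detection_rate))
  if (x$n_detected > 0) {
    cat(sprintf("Timing error (s): median %.1f (IQR %.1f-%.1f), mean %.1f, sd %.1f\n",
                x$median, x$q1, x$q3, x$mean, x$sd))
    for (nm in names(x$fraction_within)) {
      cat(sprintf("  %s: %.1f%%\n", nm, 100 * x$fraction_within[[nm]]))
    }
  }
  invisible(x)
}

#' Histogram of detection timing errors
#'
#' Bins the signed errors of an [score_detections()] summary into
#' right-open bins `[b, b + bin_width)` aligned to `origin`; counts sum to
#' the number of detected cases.
#'
#' @param summary An `error_summary`, or a numeric vector of errors.
#' @param bin_width Bin width in seconds.
#' @param origin Left edge of the bin grid; defaults to
#'   `floor(min(errors) / bin_width) * bin_width`.
#' @return Data frame with `bin_start`, `bin_end`, `count`.
#' @export
error_histogram <- function(summary, bin_width = 30, origin = NULL) {
  errors <- if (inherits(summary, "error_summary")) summary$errors else summary
  if (length(errors) == 0) stop_input("no errors to bin")
  if (bin_width <= 0) stop_config("bin_width must be positive")
  origin <- origin %||% (floor(min(errors) / bin_width) * bin_width)
  bin <- floor((errors - origin) / bin_width)
  if (any(bin < 0)) stop_input("origin must not exceed the smallest error")
  counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  data.frame(bin_start = origin + (seq_along(counts) - 1L) * bin_width,
             bin_end = origin + seq_along(counts) * bin_width,
             count = counts)
}
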