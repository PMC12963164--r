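#' Plot the ROI color trace of a case
#'
#' Red, green and blue mean ROI values (and optionally the cyan-like value)
#' against time, the standard visual check that the red value drops below
#' green and blue once the blue drape covers the bed.
#'
#' @param features Data frame from [extract_color_features()].
#' @param show_cyan Add the cyan-like trace.
#' @param onset Optional annotated draping onset (seconds since entry),
#'   drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_color_trace <- function(features, show_cyan = FALSE, onset = NULL) {
  channels <- c("R", "G", "B")
  if (show_cyan) channels <- c(channels, "cyan")
  long <- do.call(rbind, lapply(channels, function(ch) {
    data.frame(t = features$t, value = features[[ch]], channel = ch)
  }))
  long$channel <- factor(long$channel, levels = channels)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                          color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(R = "red3", G = "green4",
                                           B = "blue3", cyan = "cyan4")) +
    ggplot2::labs(x = "Time since patient entry (s)", y = "Mean ROI value",
                  color = NULL)
  if (!is.null(onset)) {
    p <- p + ggplot2::geom_vline(xintercept = onset, linetype = "dashed")
  }
  p
}

#' Plot the detection-error histogram
#'
#' @param summary An `error_summary` or numeric error vector.
#' @param bin_width Bin width in seconds.
#' @return A ggplot object with counts labeled above each bin.
#' @export
plot_error_histogram <- function(summary, bin_width = 30) {
  h <- error_histogram(summary, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.95, fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = "Detection - annotation (s)", y = "Cases")
}

#' Boxplot of action-to-incision intervals
#'
#' Five labeled boxes (first to third quartile, median line, 1.5 IQR
#' whiskers, outliers as points), one per preparatory action.
#'
#' @param table Interval table from [compute_intervals()].
#' @return A ggplot object.
#' @export
plot_interval_boxplot <- function(table) {
  long <- do.call(rbind, lapply(interval_actions, function(a) {
    data.frame(action = a, interval = table[[a]])
  }))
  long$action <- factor(long$action, levels = interval_actions,
                        labels = c("WA", "ST", "SH", "CR", "DR"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$action, y = .data$interval)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 1,
                          staplewidth = 0, color = "grey20",
                          fill = "grey90") +
    ggplot2::labs(x = NULL, y = "Interval to skin incision (min)")
}
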