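interval_actions <- c("handwash", "sterilize", "lamp", "cradle", "draping")

#' Action-to-incision intervals of a cohort
#'
#' Converts the annotation timestamps of each case into the interval, in
#' minutes, between each of the five preparatory actions and the skin
#' incision (`(incision_s - action_s) / 60`). Cases with a missing timestamp
#' are dropped with a warning; a negative interval (action recorded after
#' incision) is set to `NA` and flagged, and zero intervals are flagged but
#' kept.
#'
#' @param annotations Annotation table (see [generate_cohort()] for the
#'   schema).
#' @return Data frame with `case_id`, `department`, `robot_assisted` and one
#'   interval column per action; attribute `"flagged"` lists case/action
#'   pairs with non-positive intervals.
#' @export
compute_intervals <- function(annotations) {
  cols <- paste0(interval_actions, "_s")
  need <- c("case_id", cols, "incision_s")
  missing_cols <- setdiff(need, names(annotations))
  if (length(missing_cols)) {
    stop_input(paste("annotations lack columns:",
                     paste(missing_cols, collapse = ", ")))
  }
  complete <- stats::complete.cases(annotations[c(cols, "incision_s")])
  if (any(!complete)) {
    warning(sprintf("dropped %d case(s) with missing timestamps", sum(!complete)))
    annotations <- annotations[complete, , drop = FALSE]
  }
  out <- data.frame(case_id = annotations$case_id,
                    department = annotations$department %||% NA_character_,
                    robot_assisted = annotations$robot_assisted %||% NA,
                    stringsAsFactors = FALSE)
  flagged <- data.frame(case_id = character(0), action = character(0),
                        interval = numeric(0), stringsAsFactors = FALSE)
  for (a in interval_actions) {
    iv <- (annotations$incision_s - annotations[[paste0(a, "_s")]]) / 60
    bad <- which(iv <= 0)
    if (length(bad)) {
      flagged <- rbind(flagged, data.frame(case_id = annotations$case_id[bad],
                                           action = a, interval = iv[bad],
                                           stringsAsFactors = FALSE))
      neg <- bad[iv[bad] < 0]
      if (length(neg)) {
        warning(sprintf("excluded %d negative %s interval(s)", length(neg), a))
        iv[neg] <- NA_real_
      }
    }
    out[[a]] <- iv
  }
  attr(out, "flagged") <- flagged
  out
}

#' Summarize intervals per action
#'
#' Median, quartiles (type-7, linear interpolation), mean and standard
#' deviation of the interval to incision, in minutes, one row per action in
#' workflow-report order. With a single case the standard deviation is
#' undefined and reported as 0 with `sd_degenerate = TRUE`.
#'
#' @param table Interval table from [compute_intervals()].
#' @param actions Actions to include (default: all five).
#' @return Data frame `action, n, median, q1, q3, mean, sd, sd_degenerate`.
#' @export
summarize_intervals <- function(table, actions = interval_actions) {
  if (nrow(table) == 0) stop_input("empty interval table")
  rows <- lapply(actions, function(a) {
    v <- table[[a]]
    v <- v[is.finite(v)]
    if (length(v) == 0) stop_input(paste("no finite intervals for", a))
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(action = a, n = length(v), median = qs[2], q1 = qs[1],
               q3 = qs[3], mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               sd_degenerate = length(v) < 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Exact tie-aware null distribution of the signed-rank statistic W (sum of
# ranks of positive differences): generating function over all 2^n sign
# assignments, on doubled ranks so mid-ranks stay integral. Returns counts
# over W2 = 2*W in 0..sum(2r).
signed_rank_null_counts <- function(ranks2) {
  counts <- 1
  for (s in ranks2) {
    shifted <- c(rep(0, s), counts)
    counts <- c(counts, rep(0, s)) + shifted
  }
  counts
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are discarded before ranking
#' (Wilcoxon's original policy), ties receive mid-ranks, and the statistic
#' `W` is the sum of the ranks of positive differences. For at most
#' `exact_max` non-zero pairs the p-value comes from the exact tie-aware
#' null distribution (full enumeration of the `2^n` sign assignments via a
#' generating function); above that, a normal approximation with tie
#' correction and continuity correction is used. The two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y Paired samples (`y` omitted: `x` are the differences).
#' @param method `"auto"` (exact up to `exact_max`), `"exact"` or
#'   `"approx"`.
#' @param exact_max Largest n for the exact method under `"auto"`
#'   (default 25).
#' @return List with `statistic` (W), `n` (non-zero pairs), `p.value`,
#'   `method`, `n_zeros_dropped`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 1, 4, 2.5, 5), rep(0, 6)) # all positive, n = 6
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 method = c("auto", "exact", "approx"),
                                 exact_max = 25L) {
  method <- match.arg(method)
  d <- if (is.null(y)) x else x - y
  if (!is.null(y) && length(x) != length(y)) stop_input("x and y differ in length")
  if (any(!is.finite(d))) stop_input("differences must be finite")
  n_zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop(errorCondition("all paired differences are zero; test undefined",
                        class = c("drapewatch_degenerate_test", "error",
                                  "condition")))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (method == "auto") method <- if (n <= exact_max) "exact" else "approx"
  if (method == "exact") {
    counts <- signed_rank_null_counts(as.integer(round(2 * r)))
    total <- 2^n
    w2 <- round(2 * w)
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      stop(errorCondition("null variance is zero; test undefined",
                          class = c("drapewatch_degenerate_test", "error",
                                    "condition")))
    }
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
  }
  list(statistic = w, n = n, p.value = p, method = method,
       n_zeros_dropped = n_zeros)
}

#' Compare an action's intervals against draping
#'
#' Paired two-sided Wilcoxon signed-rank test of one action's
#' interval-to-incision against the draping interval of the same cases, with
#' Bonferroni adjustment over the four comparisons (every action other than
#' draping is tested against it).
#'
#' @param table Interval table from [compute_intervals()].
#' @param action One of `"handwash"`, `"sterilize"`, `"lamp"`, `"cradle"`.
#' @param n_comparisons Bonferroni factor (default 4).
#' @param alpha Significance level for the adjusted p (default 0.05).
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return A `paired_test_result`: `comparison`, `n_pairs`, `statistic`,
#'   `p_raw`, `p_adjusted = min(1, n_comparisons * p_raw)`, `significant`.
#' @export
signed_rank_vs_draping <- function(table, action, n_comparisons = 4L,
                                   alpha = 0.05, ...) {
  if (!action %in% setdiff(interval_actions, "draping")) {
    stop_input("action must be one of handwash, sterilize, lamp, cradle")
  }
  ok <- is.finite(table[[action]]) & is.finite(table$draping)
  res <- wilcoxon_signed_rank(table[[action]][ok], table$draping[ok], ...)
  structure(list(comparison = paste0(action, " vs draping"),
                 n_pairs = res$n, statistic = res$statistic,
                 p_raw = res$p.value,
                 p_adjusted = min(1, n_comparisons * res$p.value),
                 significant = min(1, n_comparisons * res$p.value) < alpha,
                 method = res$method),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s: W = %g, n = %d, raw p = %.3g, adjusted p = %.3g (%s)%s\n",
              x$comparison, x$statistic, x$n_pairs, x$p_raw, x$p_adjusted,
              x$method, if (x$significant) " *" else ""))
  invisible(x)
}

#' Per-stratum interval summaries
#'
#' Repeats [summarize_intervals()] within each level of a stratifying
#' variable (surgical department or robot assistance). Empty strata are
#' skipped with a warning.
#'
#' @param table Interval table from [compute_intervals()].
#' @param strata `"department"` or `"robot_assisted"`.
#' @return Data frame of per-stratum summaries with leading columns
#'   `stratum` and `n_cases`.
#' @export
subgroup_summaries <- function(table, strata = c("department", "robot_assisted")) {
  strata <- match.arg(strata)
  if (is.null(table[[strata]]) || all(is.na(table[[strata]]))) {
    stop_input(paste("stratum labels missing:", strata))
  }
  levels <- unique(table[[strata]])
  parts <- lapply(levels, function(lv) {
    sub <- table[table[[strata]] %in% lv, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("empty stratum '%s' skipped", lv))
      return(NULL)
    }
    cbind(stratum = as.character(lv), n_cases = nrow(sub),
          summarize_intervals(sub))
  })
  do.call(rbind, parts)
}

#' Headline interval comparison table
#'
#' One row per action: interval summary plus (for every action but draping)
#' the Bonferroni-adjusted paired signed-rank p-value against draping.
#'
#' @param table Interval table from [compute_intervals()].
#' @param ... Passed to [signed_rank_vs_draping()].
#' @return Data frame with summary columns and `p_adjusted`.
#' @export
compare_actions <- function(table, ...) {
  summ <- summarize_intervals(table)
  summ$p_adjusted <- NA_real_
  for (a in setdiff(interval_actions, "draping")) {
    summ$p_adjusted[summ$action == a] <-
      signed_rank_vs_draping(table, a, ...)$p_adjusted
  }
  summ
}
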