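ann_row <- function(case_id, incision, handwash, sterilize = incision - 500,
                    lamp = incision - 450, cradle = incision - 400,
                    draping = incision - 300, department = "hepatic",
                    robot = FALSE) {
  data.frame(case_id = case_id, department = department,
             robot_assisted = robot, entry_s = 0, handwash_s = handwash,
             sterilize_s = sterilize, lamp_s = lamp, cradle_s = cradle,
             draping_s = draping, incision_s = incision,
             stringsAsFactors = FALSE)
}

test_that("intervals are incision minus action, in minutes", {
  ann <- ann_row("a", incision = 1062.6, handwash = 600)
  iv <- compute_intervals(ann)
  expect_equal(iv$handwash, 7.71, tolerance = 1e-12)
})

test_that("zero intervals are flagged, negative ones excluded with a warning", {
  ann <- rbind(ann_row("a", incision = 1000, handwash = 1000),
               ann_row("b", incision = 1000, handwash = 1100))
  expect_warning(iv <- compute_intervals(ann), "negative")
  expect_equal(iv$handwash, c(0, NA_real_))
  flagged <- attr(iv, "flagged")
  expect_true(all(c("a", "b") %in% flagged$case_id))
})

test_that("cases with missing timestamps are dropped with a warning", {
  ann <- rbind(ann_row("a", incision = 1000, handwash = 400),
               ann_row("b", incision = 1000, handwash = NA))
  expect_warning(iv <- compute_intervals(ann), "missing")
  expect_equal(iv$case_id, "a")
})

test_that("summaries use type-7 quartiles and behave under translation", {
  ann <- do.call(rbind, lapply(1:3, function(i) {
    ann_row(letters[i], incision = 2000,
            handwash = 2000 - c(5.89, 7.71, 9.72)[i] * 60)
  }))
  s <- summarize_intervals(compute_intervals(ann), actions = "handwash")
  expect_equal(s$median, 7.71)
  expect_equal(s$q1, quantile(c(5.89, 7.71, 9.72), 0.25, type = 7,
                              names = FALSE))

  # single case: median = mean, sd reported 0 with degeneracy flag
  s1 <- summarize_intervals(compute_intervals(ann[1, ]), actions = "handwash")
  expect_equal(s1$median, s1$mean)
  expect_equal(s1$sd, 0)
  expect_true(s1$sd_degenerate)

  # translation equivariance
  ann2 <- ann
  ann2$handwash_s <- ann2$handwash_s - 60 # +1 minute interval
  s2 <- summarize_intervals(compute_intervals(ann2), actions = "handwash")
  expect_equal(s2$median, s$median + 1)
  expect_equal(s2$mean, s$mean + 1, tolerance = 1e-12)
  expect_equal(s2$sd, s$sd, tolerance = 1e-12)

  # permutation invariance over rows
  s3 <- summarize_intervals(compute_intervals(ann[c(3, 1, 2), ]),
                            actions = "handwash")
  expect_equal(s3, s)
  expect_error(summarize_intervals(compute_intervals(ann)[0, ]),
               class = "drapewatch_input_error")
})

test_that("six all-positive differences give exact two-sided p = 2/64", {
  res <- wilcoxon_signed_rank(c(2, 3, 1, 4, 2.5, 5), rep(0, 6))
  expect_equal(res$method, "exact")
  expect_equal(res$statistic, 21)
  expect_equal(res$p.value, 0.03125)
})

test_that("symmetric differences sit at the null center with p near 1", {
  d <- c(3, -3, 5, -5, 7, -7, 2, -2)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$statistic, sum(rank(abs(d))) / 2)
  expect_gte(res$p.value, 0.9)
  expect_error(wilcoxon_signed_rank(rep(0, 10)),
               class = "drapewatch_degenerate_test")
})

test_that("exact p matches full 2^n enumeration up to n = 12, with ties", {
  set.seed(88)
  for (n in 3:12) {
    for (rep in 1:3) {
      # discrete values force ties; mix of signs
      d <- sample(c(-4:-1, 1:4), n, replace = TRUE)
      got <- wilcoxon_signed_rank(d, method = "exact")
      expect_equal(got$p.value, signed_rank_brute_force(d), tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("the normal approximation converges to the exact p", {
  set.seed(101)
  for (rep in 1:25) {
    d <- rnorm(25, mean = runif(1, -0.5, 0.5))
    d <- d[d != 0]
    p_exact <- wilcoxon_signed_rank(d, method = "exact")$p.value
    p_approx <- wilcoxon_signed_rank(d, method = "approx")$p.value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("the approximate branch reproduces the reference implementation", {
  set.seed(55)
  for (rep in 1:20) {
    x <- rnorm(40)
    y <- rnorm(40, 0.3)
    got <- wilcoxon_signed_rank(x, y, method = "approx")$p.value
    want <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # ties as well
  x <- sample(1:5, 40, replace = TRUE)
  y <- sample(1:5, 40, replace = TRUE)
  d_ok <- sum(x != y) > 0
  if (d_ok) {
    got <- wilcoxon_signed_rank(x, y, method = "approx")$p.value
    want <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment is monotone, capped and applied fourfold", {
  coh <- generate_cohort(cohort_config(n_cases = 60, seed = 17))
  iv <- compute_intervals(coh)
  res <- signed_rank_vs_draping(iv, "sterilize")
  expect_equal(res$p_adjusted, min(1, 4 * res$p_raw))
  expect_true(res$p_adjusted >= res$p_raw)
  # tiny cohort with no real effect: adjusted p caps at 1
  tiny <- iv[1:6, ]
  tiny$handwash <- tiny$draping + c(0.01, -0.01, 0.02, -0.02, 0.03, -0.03)
  res2 <- signed_rank_vs_draping(tiny, "handwash")
  expect_lte(res2$p_adjusted, 1)
  expect_error(signed_rank_vs_draping(iv, "draping"),
               class = "drapewatch_input_error")
})

test_that("draping separates from every other action in seeded cohorts", {
  hits <- 0
  for (rep in 1:30) {
    coh <- generate_cohort(cohort_config(n_cases = 110, seed = 7000 + rep))
    iv <- compute_intervals(coh)
    res <- signed_rank_vs_draping(iv, "sterilize")
    if (res$significant) hits <- hits + 1
  }
  expect_gte(hits, 29)
})

test_that("subgroup summaries report exact stratum sizes", {
  coh <- generate_cohort(cohort_config(n_cases = 110, seed = 13))
  iv <- compute_intervals(coh)
  sub <- subgroup_summaries(iv, "robot_assisted")
  sizes <- unique(sub[, c("stratum", "n_cases")])
  expect_setequal(sizes$n_cases, c(30, 80))

  # a single-stratum cohort reproduces the global summary
  iv1 <- iv
  iv1$department <- "hepatic"
  sub1 <- subgroup_summaries(iv1, "department")
  glob <- summarize_intervals(iv1)
  expect_equal(sub1$median, glob$median)
  expect_equal(sub1$sd, glob$sd)
})

test_that("per-stratum generation recovers the stratum's own medians", {
  rb <- action_interval_defaults("robot")
  coh <- generate_cohort(cohort_config(n_cases = 3000, actions = rb,
                                       prop_robot = 1, seed = 77))
  summ <- summarize_intervals(compute_intervals(coh))
  m <- summ$median[summ$action == "draping"]
  expect_lt(abs(m - 9.53) / 9.53, 0.05)
})

test_that("the headline comparison table pairs summaries with adjusted p", {
  coh <- generate_cohort(cohort_config(n_cases = 110, seed = 19))
  tab <- compare_actions(compute_intervals(coh))
  expect_equal(tab$action,
               c("handwash", "sterilize", "lamp", "cradle", "draping"))
  expect_true(all(is.finite(tab$p_adjusted[tab$action != "draping"])))
  expect_true(is.na(tab$p_adjusted[tab$action == "draping"]))
  expect_equal(which.min(tab$median), 5L)
})
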