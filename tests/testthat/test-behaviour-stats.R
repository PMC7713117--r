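test_that("rtcv is SD/mean with the n-1 denominator", {
  expect_equal(rtcv(c(400, 400, 400)), 0)
  expect_equal(rtcv(c(300, 500)), 0.35355, tolerance = 1e-4)
  x <- c(310, 420, 388, 505, 441)
  expect_equal(rtcv(7 * x), rtcv(x)) # scale invariance
  expect_invalid(rtcv(c(500)))
  expect_invalid(rtcv(c(-300, 100)))
})

test_that("error rate and breath accuracy follow their definitions", {
  expect_equal(error_rate(0, 800), 0)
  expect_equal(error_rate(4, 800), 0.5)
  flags <- c(rep(TRUE, 3), rep(FALSE, 797))
  expect_equal(error_rate(flags), 3 / 800 * 100)
  expect_lte(error_rate(flags), error_rate(c(rep(TRUE, 4), rep(FALSE, 796))))

  expect_equal(breath_accuracy(15, 20), 75)
  expect_equal(breath_accuracy(20, 20), 100)
  cycles <- c(rep("correct", 12), rep("self_caught", 3), rep("incorrect", 5))
  expect_equal(breath_accuracy(cycles), 60) # self-caught counted incorrect
})

test_that("pooled-variance t reproduces printed summary statistics", {
  breath <- independent_t(
    list(mean = 44.8, sd = 32.7, n = 50),
    list(mean = 53.4, sd = 34.8, n = 31)
  )
  expect_lt(abs(abs(breath$t) - 1.12), 0.02)
  expect_identical(breath$df, 79)

  rt <- independent_t(
    list(mean = 433.3, sd = 48.6, n = 50),
    list(mean = 436.3, sd = 56.9, n = 31)
  )
  expect_lt(abs(abs(rt$t) - 0.25), 0.02)
})

test_that("summary and raw entry points of independent_t agree exactly", {
  set.seed(20)
  x <- rnorm(14, 10, 2)
  y <- rnorm(9, 11, 3)
  raw <- independent_t(x, y)
  summ <- independent_t(
    list(mean = mean(x), sd = sd(x), n = length(x)),
    list(mean = mean(y), sd = sd(y), n = length(y))
  )
  expect_equal(raw$t, summ$t)
  expect_equal(raw$hedges_g, summ$hedges_g)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$t, unname(ref$statistic))
  expect_equal(raw$p_value, ref$p.value)

  expect_equal(independent_t(x, x)$t, 0)
  expect_equal(independent_t(rep(1, 5), rep(1, 5))$t, 0) # fully degenerate
  expect_error(independent_t(rep(1, 5), rep(2, 5)),
    class = "erpcluster_undefined_statistic"
  )
})

test_that("paired t matches its hand-computed value and is antisymmetric", {
  res <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_identical(res$df, 2L)

  set.seed(21)
  a <- rnorm(12)
  b <- rnorm(12)
  fwd <- paired_t(a, b)
  rev_ <- paired_t(b, a)
  expect_equal(fwd$t, -rev_$t)
  expect_equal(abs(fwd$hedges_g), abs(rev_$hedges_g))
  expect_equal(fwd$t, unname(t.test(a, b, paired = TRUE)$statistic))
  expect_equal(paired_t(a, a)$t, 0) # identical timepoints: t = 0
  expect_error(paired_t(c(2, 2, 2), c(1, 1, 1)),
    class = "erpcluster_undefined_statistic"
  )
})

# textbook split-plot decomposition used as an independent oracle
splitplot_oracle <- function(tbl) {
  wide <- tidyr::pivot_wider(tbl,
    names_from = "timepoint",
    values_from = "y"
  )
  y <- as.matrix(wide[, -(1:2)])
  g <- wide$group
  n <- nrow(y)
  k <- ncol(y)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  time_means <- colMeans(y)
  group_means <- tapply(subj_means, g, mean)
  cell_means <- rowsum(y, g) / as.vector(table(g))
  ss_group <- k * sum(as.vector(table(g)) * (group_means - grand)^2)
  ss_subj_within <- k * sum((subj_means - group_means[g])^2)
  ss_time <- n * sum((time_means - grand)^2)
  ss_cells <- 0
  for (gi in rownames(cell_means)) {
    ng <- sum(g == gi)
    ss_cells <- ss_cells + ng * sum((cell_means[gi, ] - grand)^2)
  }
  ss_gt <- ss_cells - ss_group - ss_time
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_group - ss_subj_within - ss_time - ss_gt
  list(
    group = ss_group, subj = ss_subj_within, time = ss_time,
    gt = ss_gt, err = ss_err,
    F_group = (ss_group / (length(unique(g)) - 1)) /
      (ss_subj_within / (n - length(unique(g)))),
    F_time = (ss_time / (k - 1)) /
      (ss_err / ((n - length(unique(g))) * (k - 1))),
    F_gt = (ss_gt / ((length(unique(g)) - 1) * (k - 1))) /
      (ss_err / ((n - length(unique(g))) * (k - 1)))
  )
}

test_that("the mixed ANOVA matches a textbook split-plot decomposition", {
  set.seed(22)
  tbl <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:12),
    timepoint = c("T1", "T2", "T3")
  ) |>
    dplyr::mutate(
      group = rep(c("MT", "CT"), each = 18),
      y = rnorm(36, 10) + rep(c(0, 0.5, 1), 12) +
        ifelse(group == "MT", rep(c(0, 1, 2), 12), 0)
    )
  fit <- mixed_anova(tbl, "y")
  td <- tidy(fit)
  oracle <- splitplot_oracle(tbl)
  expect_equal(td$F[td$effect == "group"], oracle$F_group)
  expect_equal(td$F[td$effect == "time"], oracle$F_time)
  expect_equal(td$F[td$effect == "group x time"], oracle$F_gt)
  expect_equal(td$df1, c(1, 2, 2))
  expect_equal(td$df2, c(10, 20, 20))
  # grand decomposition: total SS equals the sum of all components
  total <- sum((tbl$y - mean(tbl$y))^2)
  expect_equal(
    oracle$group + oracle$subj + oracle$time + oracle$gt + oracle$err,
    total
  )
})

test_that("a two-level within factor reduces the ANOVA F to the paired t squared", {
  set.seed(23)
  tbl <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:10), timepoint = c("T1", "T2")
  ) |> dplyr::mutate(group = "MT", y = rnorm(20) + (timepoint == "T2") * 0.8)
  fit <- mixed_anova(tbl, "y")
  wide <- tidyr::pivot_wider(tbl, names_from = "timepoint", values_from = "y")
  tt <- paired_t(wide$T2, wide$T1)
  expect_equal(tidy(fit)$F, tt$t^2)
  expect_equal(tidy(fit)$p_value, tt$p_value)
})

test_that("degenerate and unbalanced ANOVA inputs are handled", {
  tbl <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:8), timepoint = c("T1", "T2", "T3")
  ) |> dplyr::mutate(group = rep(c("MT", "CT"), each = 12), y = 5)
  fit <- mixed_anova(tbl, "y")
  expect_true(all(tidy(fit)$F == 0))
  expect_true(all(tidy(fit)$p_value == 1))

  # subjects missing a timepoint are dropped with a logged count
  tbl2 <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:8), timepoint = c("T1", "T2", "T3")
  ) |> dplyr::mutate(
    group = rep(c("MT", "CT"), each = 12),
    y = rnorm(24)
  )
  tbl2 <- tbl2[-1, ] # s01 loses T1
  fit2 <- mixed_anova(tbl2, "y")
  expect_identical(glance(fit2)$n_dropped, 1L)
  expect_identical(glance(fit2)$n_subjects, 7L)
  # statistics do not depend on row order
  fit3 <- mixed_anova(tbl2[sample(nrow(tbl2)), ], "y")
  expect_equal(tidy(fit2)$F, tidy(fit3)$F)
})

# literal step-up definition over every candidate rejection count
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord][i] <= q * i / m) k <- i
  rejected <- logical(m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

test_that("BH-FDR matches the brute-force step-up oracle", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$rejected))
  expect_true(all(bh_fdr(rep(1, 5))$rejected == FALSE))

  set.seed(24)
  for (i in 1:20) {
    p <- round(runif(sample(3:8, 1)), 3)
    res <- bh_fdr(p, q = 0.05)
    expect_identical(res$rejected, bh_oracle(p, 0.05))
    expect_equal(res$p_adjusted, p.adjust(p, "BH"))
    # adjusted values monotone in sorted order
    expect_true(!is.unsorted(res$p_adjusted[order(p)]))
    # step-up rejection coincides with adjusted p <= q
    expect_identical(res$rejected, res$p_adjusted <= 0.05)
  }
  expect_invalid(bh_fdr(c(0.5, 1.2)))
})

test_that("the percentile outlier screen flags the documented tails", {
  res <- percentile_outliers(1:100)
  expect_identical(which(res$flag), c(1:5, 96:100))
  expect_identical(res$n_flagged, 10L)

  expect_identical(percentile_outliers(rep(3, 20))$n_flagged, 0L)

  set.seed(25)
  for (i in 1:10) {
    x <- rnorm(sample(10:60, 1))
    res <- percentile_outliers(x)
    expect_lte(res$n_flagged, 0.1 * length(x) + 2)
  }
  expect_warning(res <- percentile_outliers(1:5), "fewer than 10")
  expect_identical(res$n_flagged, 0L)
})
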