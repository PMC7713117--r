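members_for <- function(channel_idx, samples, times_ms) {
  tidyr::expand_grid(channel_idx = channel_idx, sample = samples) |>
    dplyr::mutate(
      channel = sprintf("E%03d", channel_idx),
      time_ms = times_ms[sample], stat = 3, point = dplyr::row_number()
    )
}

test_that("trapezoid AUC is exact on piecewise-linear waveforms", {
  # triangle (0, 1, 0) over 0..20 ms
  mat <- matrix(c(0, 1, 0), 1, byrow = TRUE)
  mat <- rbind(mat, mat) # two identical channels
  mem <- members_for(1:2, 1:3, c(0, 10, 20))
  expect_equal(cluster_auc(mat, mem, times_ms = c(0, 10, 20)), 10)

  # rectangle: constant 1 over 100 ms
  n <- 11
  mat2 <- matrix(1, 2, n)
  mem2 <- members_for(1:2, 1:n, seq(0, 100, by = 10))
  expect_equal(cluster_auc(mat2, mem2, times_ms = seq(0, 100, by = 10)), 100)

  # linearity in voltage scale
  mat3 <- matrix(rnorm(2 * n), 2, n)
  mem3 <- mem2
  a <- cluster_auc(mat3, mem3, times_ms = seq(0, 100, by = 10))
  a5 <- cluster_auc(5 * mat3, mem3, times_ms = seq(0, 100, by = 10))
  expect_equal(a5, 5 * a)

  # closed form for an arbitrary piecewise-linear waveform
  ts <- c(0, 4, 10, 25)
  wave <- c(0, 2, -1, 3)
  mat4 <- rbind(wave, wave)
  mem4 <- members_for(1:2, 1:4, ts)
  closed <- sum(diff(ts) * (head(wave, -1) + wave[-1]) / 2)
  expect_equal(cluster_auc(mat4, mem4, times_ms = ts), closed)
})

test_that("AUC over an erp_stack returns one signed value per observation", {
  dat <- array(0, c(2, 2, 2))
  dat[1, , ] <- 1
  dat[2, , ] <- -1
  st <- stack_from_array(dat, sfreq = 1000)
  mem <- members_for(1:2, 1:2, c(0, 1))
  out <- cluster_auc(st, mem)
  expect_identical(nrow(out), 2L)
  expect_equal(out$auc_uv_ms, c(1, -1)) # 1 ms extent, amplitudes +/-1
})

test_that("member-exact masking differs from the rectangular hull when ragged", {
  mat <- rbind(c(1, 1, 1), c(10, 10, 10))
  mem <- tibble::tibble(
    channel_idx = c(1L, 1L, 1L, 2L), sample = c(1L, 2L, 3L, 2L),
    channel = sprintf("E%03d", channel_idx), time_ms = c(0, 10, 20, 10),
    stat = 3, point = 1:4
  )
  hull <- cluster_auc(mat, mem, times_ms = c(0, 10, 20))
  exact <- cluster_auc(mat, mem, member_exact = TRUE, times_ms = c(0, 10, 20))
  expect_equal(hull, 20 * 5.5) # both channels, full 20 ms
  expect_gt(abs(hull - exact), 1) # sample 2 averages both, others only ch1
})

test_that("Pearson correlation matches hand values with Fisher-z interval", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 4))
  res <- correlate(d, "x", "y")
  expect_equal(res$r, 0.982, tolerance = 1e-3)
  expect_identical(res$df, 1L)

  d2 <- tibble::tibble(x = 1:6, y = 2 * (1:6) + 1)
  res2 <- correlate(d2, "x", "y")
  expect_equal(res2$r, 1)

  set.seed(3)
  d3 <- tibble::tibble(x = rnorm(40), y = rnorm(40))
  res3 <- correlate(d3, "x", "y")
  ref <- cor.test(d3$x, d3$y)
  expect_equal(res3$r, unname(ref$estimate))
  expect_equal(res3$p_value, ref$p.value)
  expect_equal(c(res3$conf_low, res3$conf_high), as.numeric(ref$conf.int))
  expect_true(res3$conf_low <= res3$r && res3$r <= res3$conf_high)
})

test_that("correlation is invariant under positive affine transforms", {
  set.seed(4)
  d <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  base <- correlate(d, "x", "y")
  d2 <- dplyr::mutate(d, x = 3 * x + 10, y = 0.5 * y - 2)
  expect_equal(correlate(d2, "x", "y")$r, base$r)
})

test_that("missing pairs are dropped and reflected in n; zero variance errors", {
  d <- tibble::tibble(x = c(1, 2, 3, NA, 5, 6), y = c(2, 1, 4, 5, NA, 7))
  res <- correlate(d, "x", "y")
  expect_identical(res$n, 4L)
  expect_identical(res$df, 2L)
  expect_error(
    correlate(tibble::tibble(x = rep(1, 6), y = rnorm(6)), "x", "y"),
    class = "erpcluster_undefined_correlation"
  )
  expect_invalid(correlate(tibble::tibble(x = 1:2, y = 1:2), "x", "y"))
})

test_that("a planted amplitude-RT coupling is recovered through the AUC path", {
  ok <- 0L
  for (seed in 1:50) {
    plan <- one_component_plan(
      base = 2, subject_sd = 0.2, trial_sd = 3,
      couplings = tibble::tibble(component = "C1", r = 0.3)
    )
    plan$subject_rt_sd_log <- 0.01
    plan$behaviour <- tidyr::expand_grid(
      group = c("MT", "CT"), timepoint = c("T1", "T2", "T3")
    ) |> dplyr::mutate(
      rt_mean_ms = 433, rt_cv = 0.14, error_prob = 0,
      breath_mean = 50, breath_sd = 10
    )
    m <- make_montage(8, "reduced-head")
    st <- simulate_erp_study(
      list(groups = c(MT = 40, CT = 2), timepoints = c("T1", "T2", "T3")),
      m, plan,
      noise = noise_spec(sd = 1), seed = seed, n_trials = 10,
      sfreq = 128, t_start = -0.1, t_end = 0.2, stim_classes = "cue"
    )$cue
    mask <- component_mask(
      plan$components[[1]], m, st$sfreq, st$t_start,
      dim(st$data)[3]
    )
    mem <- tibble::tibble(
      channel_idx = rep(mask$channels, length(mask$samples)),
      sample = rep(mask$samples, each = length(mask$channels)),
      channel = sprintf("E%03d", channel_idx),
      time_ms = 0, stat = 3, point = seq_along(channel_idx)
    )
    auc <- cluster_auc(st, mem)
    pooled <- auc[auc$group == "MT", ]
    if (cor(pooled$auc_uv_ms, pooled$rt_ms) > 0) ok <- ok + 1L
  }
  expect_gte(ok, 45L) # positive pooled correlation in >= 90% of runs
})

test_that("group-level brain-behaviour pooling reports exclusions and df", {
  set.seed(6)
  n <- 20L
  auc_tbl <- tidyr::expand_grid(
    subject = sprintf("MT%03d", 1:n), timepoint = c("T1", "T2", "T3")
  ) |> dplyr::mutate(group = "MT", auc_uv_ms = rnorm(dplyr::n(), 0, 50))
  beh <- dplyr::mutate(auc_tbl[, c("subject", "timepoint", "group")],
    rt_mean_ms = 430 + 0.1 * auc_tbl$auc_uv_ms + rnorm(3 * n, 0, 5)
  )
  res <- correlate_brain_behaviour(auc_tbl, beh)
  expect_identical(nrow(res$pooled), 1L)
  expect_identical(res$pooled$n + res$pooled$n_excluded, 3L * n)
  expect_identical(res$pooled$df, res$pooled$n - 2L)
  expect_gt(res$pooled$r, 0)
  expect_identical(nrow(res$per_timepoint), 3L)
})
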