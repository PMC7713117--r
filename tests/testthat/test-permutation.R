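test_that("the four-subject constant example gives exhaustive p = 2/6", {
  d <- array(rep(c(0, 0, 10, 10), 2), c(4, 2, 1))
  st <- stack_from_array(d, group = rep(c("A", "B"), each = 2))
  res <- permutation_test(st, "t-independent",
    cond = "group", levels = c("A", "B"),
    cfg = stat_config(mode = "exhaustive", analysis_window_ms = NULL)
  )
  expect_identical(res$mode, "exhaustive")
  expect_identical(res$n_partitions, 6)
  expect_equal(res$clusters$p_value, 2 / 6)
  expect_true(res$clusters$significant == FALSE)
})

test_that("monte-carlo is refused when fewer than 10 distinct partitions exist", {
  d <- array(rnorm(8), c(4, 2, 1))
  st <- stack_from_array(d, group = rep(c("A", "B"), each = 2))
  expect_invalid(permutation_test(st, "t-independent",
    cond = "group",
    cfg = stat_config(mode = "monte-carlo", analysis_window_ms = NULL)
  ))
})

test_that("results are reproducible under a fixed seed", {
  st <- make_null_erp_stack(c(8, 8), 6, 40, seed = 3)
  cfg <- stat_config(
    n_permutations = 100, seed = 42,
    analysis_window_ms = NULL, mode = "monte-carlo"
  )
  a <- permutation_test(st, "t-independent", cond = "group", cfg = cfg)
  b <- permutation_test(st, "t-independent", cond = "group", cfg = cfg)
  expect_identical(a$null_dist, b$null_dist)
  expect_identical(a$clusters$p_value, b$clusters$p_value)
})

test_that("monte-carlo p agrees with the exhaustive oracle on small instances", {
  set.seed(8)
  base <- array(rnorm(8 * 4 * 20, sd = 1), c(8, 4, 20))
  base[5:8, 1:2, 5:12] <- base[5:8, 1:2, 5:12] + 1.2 # moderate group effect
  st <- stack_from_array(base, group = rep(c("A", "B"), each = 4))
  adj <- build_adjacency(st$montage, "distance", threshold = 1.5)
  ex <- permutation_test(st, "t-independent",
    cond = "group", adjacency = adj,
    cfg = stat_config(mode = "exhaustive", analysis_window_ms = NULL)
  )
  mc <- permutation_test(st, "t-independent",
    cond = "group", adjacency = adj,
    cfg = stat_config(
      mode = "monte-carlo", n_permutations = 5000, seed = 1,
      analysis_window_ms = NULL
    )
  )
  expect_identical(ex$n_partitions, choose(8, 4))
  expect_gt(nrow(ex$clusters), 0)
  for (i in seq_len(min(3, nrow(ex$clusters)))) {
    p_ex <- ex$clusters$p_value[i]
    p_mc <- mc$clusters$p_value[i]
    tol <- 3 * sqrt(p_ex * (1 - p_ex) / 5000) + 2 / 5001
    expect_lt(abs(p_mc - p_ex), tol + 1e-12)
  }
})

test_that("swapping group labels negates masses but keeps p-values", {
  set.seed(9)
  d <- array(rnorm(12 * 3 * 15), c(12, 3, 15))
  d[1:6, , 4:9] <- d[1:6, , 4:9] + 1.5
  st <- stack_from_array(d, group = rep(c("A", "B"), each = 6))
  cfg <- stat_config(mode = "exhaustive", analysis_window_ms = NULL)
  adj <- build_adjacency(st$montage, "distance", threshold = 1.5)
  ab <- permutation_test(st, "t-independent",
    cond = "group",
    levels = c("A", "B"), adjacency = adj, cfg = cfg
  )
  ba <- permutation_test(st, "t-independent",
    cond = "group",
    levels = c("B", "A"), adjacency = adj, cfg = cfg
  )
  oab <- ab$clusters
  oba <- ba$clusters
  expect_equal(sort(abs(oab$mass)), sort(abs(oba$mass)))
  expect_equal(
    oab$p_value[order(-abs(oab$mass))],
    oba$p_value[order(-abs(oba$mass))]
  )
  expect_equal(max(ab$clusters$mass), -min(ba$clusters$mass))
})

test_that("shifting one group towards the max cluster cannot shrink it", {
  set.seed(11)
  d <- array(rnorm(10 * 3 * 12), c(10, 3, 12))
  d[1:5, , 4:8] <- d[1:5, , 4:8] + 1 # positive observed max cluster
  st <- stack_from_array(d, group = rep(c("A", "B"), each = 5))
  adj <- build_adjacency(st$montage, "distance", threshold = 1.5)
  cfg <- stat_config(mode = "exhaustive", analysis_window_ms = NULL)
  base <- permutation_test(st, "t-independent",
    cond = "group",
    levels = c("A", "B"), adjacency = adj, cfg = cfg
  )
  d2 <- d
  d2[1:5, , ] <- d2[1:5, , ] + 0.5
  st2 <- stack_from_array(d2, group = rep(c("A", "B"), each = 5))
  shifted <- permutation_test(st2, "t-independent",
    cond = "group",
    levels = c("A", "B"), adjacency = adj, cfg = cfg
  )
  expect_gte(
    max(abs(shifted$clusters$mass)),
    max(abs(base$clusters$mass))
  )
})

test_that("relabelling channels permutes members but not masses or p-values", {
  set.seed(12)
  d <- array(rnorm(10 * 4 * 12), c(10, 4, 12))
  d[1:5, 1:2, 3:9] <- d[1:5, 1:2, 3:9] + 1.5
  st <- stack_from_array(d, group = rep(c("A", "B"), each = 5))
  adj <- build_adjacency(st$montage, "distance", threshold = 1.5)
  cfg <- stat_config(mode = "exhaustive", analysis_window_ms = NULL)
  base <- permutation_test(st, "t-independent",
    cond = "group",
    levels = c("A", "B"), adjacency = adj, cfg = cfg
  )
  # reverse the channel axis and the adjacency with it
  perm <- 4:1
  d2 <- d[, perm, , drop = FALSE]
  st2 <- stack_from_array(d2, group = rep(c("A", "B"), each = 5))
  adj2 <- build_adjacency(st2$montage, "distance", threshold = 1.5)
  relab <- permutation_test(st2, "t-independent",
    cond = "group",
    levels = c("A", "B"), adjacency = adj2, cfg = cfg
  )
  expect_equal(sort(base$clusters$mass), sort(relab$clusters$mass))
  expect_equal(
    base$clusters$p_value[order(base$clusters$mass)],
    relab$clusters$p_value[order(relab$clusters$mass)]
  )
  expect_identical(base$null_dist, relab$null_dist)
})

test_that("paired and interaction designs honour their permutation units", {
  set.seed(13)
  n <- 6
  t1 <- replicate(n, matrix(rnorm(2 * 10), 2), simplify = FALSE)
  t3 <- lapply(t1, function(m) m + matrix(rnorm(2 * 10, 0.4), 2))
  st <- paired_stack(t1, t3)
  res <- permutation_test(st, "t-paired",
    cond = "timepoint",
    levels = c("T3", "T1"),
    cfg = stat_config(mode = "exhaustive", analysis_window_ms = NULL)
  )
  expect_identical(res$n_partitions, 2^n)
  expect_identical(length(res$null_dist), as.integer(2^n))

  # interaction: identical change in both groups leaves nothing significant
  info <- tibble::tibble(
    subject = rep(sprintf("s%d", 1:8), 2),
    group = rep(rep(c("A", "B"), each = 4), 2),
    timepoint = rep(c("T1", "T3"), each = 8)
  )
  d <- array(rnorm(16 * 2 * 10), c(16, 2, 10))
  d[9:16, , ] <- d[9:16, , ] + 2 # same shift at T3 for both groups
  sti <- erp_stack(d, info, 256, 0, make_montage(2, "grid"))
  ri <- interaction_contrast(sti,
    times = c("T1", "T3"),
    cfg = stat_config(mode = "exhaustive", analysis_window_ms = NULL)
  )
  expect_identical(ri$design, "t-independent")
  expect_identical(ri$n_partitions, choose(8, 4))
  expect_true(all(!ri$clusters$significant))

  # unmatched subjects are rejected
  bad <- sti
  bad$info$subject[1] <- "zz"
  expect_invalid(interaction_contrast(bad, times = c("T1", "T3")))
})

test_that("cluster-masked Cohen's d matches its definition and is scale-free", {
  # per-subject paired differences 1, 2, 3 over the whole (tiny) map
  t1 <- replicate(3, matrix(0, 2, 2), simplify = FALSE)
  t3 <- lapply(1:3, function(i) matrix(i, 2, 2))
  st <- paired_stack(t1, t3)
  members <- tibble::tibble(
    channel = rep(c("E001", "E002"), 2), channel_idx = rep(1:2, 2),
    sample = rep(1:2, each = 2), time_ms = 0,
    stat = 1, point = c(1L, 2L, 3L, 4L)
  )
  d <- cluster_effect_size(st, members,
    design = "t-paired",
    cond = "timepoint", levels = c("T3", "T1")
  )
  expect_equal(d, 2.0) # mean 2 / sd 1

  st_scaled <- st
  st_scaled$data <- st$data * 7
  expect_equal(
    cluster_effect_size(st_scaled, members,
      design = "t-paired",
      cond = "timepoint", levels = c("T3", "T1")
    ),
    2.0
  )

  # zero variance of the scalars: signed infinity
  t3c <- replicate(3, matrix(1, 2, 2), simplify = FALSE)
  stc <- paired_stack(t1, t3c)
  expect_identical(
    cluster_effect_size(stc, members,
      design = "t-paired",
      cond = "timepoint", levels = c("T3", "T1")
    ),
    Inf
  )
})

test_that("null p-values of the max-cluster statistic are uniform", {
  # exhaustive paired design: p lives on the grid k/256 and must be uniform
  pvals <- vapply(1:200, function(seed) {
    st <- make_null_erp_stack(c(8, 8), 4, 30, seed = seed)
    info <- st$info
    info$timepoint <- rep(c("T1", "T3"), each = 8)
    info$subject <- rep(sprintf("s%d", 1:8), 2)
    stp <- erp_stack(st$data, info, st$sfreq, st$t_start, st$montage)
    res <- permutation_test(stp, "t-paired",
      cond = "timepoint",
      levels = c("T3", "T1"),
      cfg = stat_config(
        mode = "exhaustive", analysis_window_ms = NULL,
        min_simultaneous_channels = 1
      )
    )
    # p of the maximum-mass cluster: uniform on its 1/256 grid under the null
    if (nrow(res$clusters)) res$clusters$p_value[1] else 1
  }, numeric(1))
  expect_true(all(pvals > 0 & pvals <= 1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
})
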