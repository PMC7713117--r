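#' Configuration of the cluster permutation test
#'
#' @param alpha Family-wise significance level for clusters (default 0.05,
#'   two-tailed: positive and negative clusters are formed separately and
#'   compared against the null distribution of the maximum absolute cluster
#'   mass pooled over signs).
#' @param n_permutations Random partitions drawn in monte-carlo mode
#'   (default 5000).
#' @param min_simultaneous_channels Minimum channels a cluster must span at
#'   every time sample; thinner time-slices are pruned (default 2).
#' @param analysis_window_ms Window the test is restricted to, ms (default
#'   0-600 post-stimulus); `NULL` = full epoch.
#' @param cluster_alpha Alpha of the pointwise cluster-forming critical value
#'   (two-tailed for t maps, upper tail for F). `NULL` (default) uses
#'   `alpha`; set 0.025 for the per-tail convention.
#' @param seed Integer seed for the random partitions.
#' @param mode `"auto"` (exhaustive when the full enumeration is at most
#'   `exhaustive_cap`, else monte-carlo), `"monte-carlo"` or `"exhaustive"`.
#' @param exhaustive_cap Largest enumeration size run exhaustively.
#' @return List of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, n_permutations = 5000,
                        min_simultaneous_channels = 2,
                        analysis_window_ms = c(0, 600),
                        cluster_alpha = NULL, seed = NULL,
                        mode = c("auto", "monte-carlo", "exhaustive"),
                        exhaustive_cap = 20000) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  if (n_permutations < 1) stop_invalid("n_permutations must be >= 1")
  if (min_simultaneous_channels < 1) {
    stop_invalid("min_simultaneous_channels must be >= 1")
  }
  structure(
    list(
      alpha = alpha, n_permutations = as.integer(n_permutations),
      min_simultaneous_channels = as.integer(min_simultaneous_channels),
      analysis_window_ms = analysis_window_ms,
      cluster_alpha = cluster_alpha, seed = seed,
      mode = match.arg(mode), exhaustive_cap = exhaustive_cap
    ),
    class = "stat_config"
  )
}

# number of distinct label partitions for a prepared design
n_partitions_of <- function(prep) {
  switch(prep$design,
    "t-independent" = choose(prep$n, prep$n1),
    "t-paired" = 2^prep$n,
    "F-repeated" = factorial(prep$k)^prep$n
  )
}

# statistic vector under one partition
perm_stat <- function(prep, part) {
  switch(prep$design,
    "t-independent" = t_independent_vec(prep$X, prep$X2, part),
    "t-paired" = t_paired_vec(prep$D, prep$cs2, part),
    "F-repeated" = f_repeated_vec(prep$Xs, part, prep$ss_within_total, prep$ss_tol)
  )
}

identity_partition <- function(prep) {
  switch(prep$design,
    "t-independent" = prep$g1,
    "t-paired" = rep(1, prep$n),
    "F-repeated" = matrix(rep(seq_len(prep$k), each = prep$n), prep$n)
  )
}

random_partition <- function(prep) {
  switch(prep$design,
    "t-independent" = {
      g <- logical(prep$n)
      g[sample.int(prep$n, prep$n1)] <- TRUE
      g
    },
    "t-paired" = sample(c(-1, 1), prep$n, replace = TRUE),
    "F-repeated" = t(vapply(
      seq_len(prep$n),
      function(i) sample.int(prep$k), integer(prep$k)
    ))
  )
}

# exhaustive enumeration as a list of partitions (includes the identity)
enumerate_partitions <- function(prep) {
  switch(prep$design,
    "t-independent" = {
      sets <- utils::combn(prep$n, prep$n1, simplify = FALSE)
      lapply(sets, function(s) {
        g <- logical(prep$n)
        g[s] <- TRUE
        g
      })
    },
    "t-paired" = {
      lapply(seq_len(2^prep$n) - 1L, function(b) {
        bits <- as.integer(intToBits(b))[seq_len(prep$n)]
        ifelse(bits == 1L, -1, 1)
      })
    },
    "F-repeated" = {
      perms_k <- all_permutations(prep$k)
      m <- length(perms_k)
      total <- m^prep$n
      lapply(seq_len(total) - 1L, function(code) {
        a <- matrix(0L, prep$n, prep$k)
        for (i in seq_len(prep$n)) {
          a[i, ] <- perms_k[[code %% m + 1L]]
          code <- code %/% m
        }
        a
      })
    }
  )
}

all_permutations <- function(k) {
  if (k == 1L) {
    return(list(1L))
  }
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Spatiotemporal cluster-based permutation test
#'
#' The package's core inference engine. At every (channel, sample) point a
#' pointwise statistic is computed for the requested design; suprathreshold
#' points are clustered by spatiotemporal connectivity and each cluster's
#' mass is the sum of its statistic values. The null distribution of the
#' maximum absolute cluster mass is built by exchanging labels at the
#' design's permutation unit (group labels across subjects for independent
#' designs; condition labels within subject for paired and repeated-measures
#' designs), and each observed cluster's p-value is the proportion of
#' partitions whose maximum mass reaches its own (identity partition
#' included, ties counted against the observed cluster). Clusters with
#' p <= alpha are flagged significant; this controls the family-wise error
#' rate over all channels and samples.
#'
#' @inheritParams pointwise_stat
#' @param adjacency Channel `adjacency`; `NULL` builds the montage default.
#' @param cfg A [stat_config()].
#' @return A `cluster_result`: list with `clusters` (tibble, one row per
#'   observed cluster with `mass`, `p_value`, `effect_size_d`,
#'   `significant`, time extent and channel counts, plus a `members`
#'   list-column), `null_dist`, `stat_map`, `config`, `mode`,
#'   `n_partitions`, and design bookkeeping.
#' @examples
#' stack <- make_null_erp_stack(c(6, 6), n_channels = 8, n_samples = 40, seed = 2)
#' res <- permutation_test(stack,
#'   design = "t-independent",
#'   cfg = stat_config(n_permutations = 200, analysis_window_ms = NULL, seed = 1)
#' )
#' tidy(res)
#' @export
permutation_test <- function(stack, design = c(
                               "t-independent", "t-paired",
                               "F-repeated"
                             ),
                             cond = if (design[1] == "t-independent") "group" else "timepoint",
                             levels = NULL, subject = "subject",
                             adjacency = NULL, cfg = stat_config()) {
  design <- match.arg(design)
  if (!is.null(cfg$analysis_window_ms)) {
    idx <- window_to_idx(
      cfg$analysis_window_ms, stack$sfreq, stack$t_start,
      dim(stack$data)[3]
    )
    stack <- stack_crop_idx(stack, idx)
  }
  if (is.null(adjacency)) adjacency <- build_adjacency(stack$montage)
  prep <- prepare_design(stack, design, cond, levels, subject)
  map <- pointwise_stat(stack, design, cond, levels, subject)
  thr <- cluster_forming_threshold(map, cfg)
  signed <- design != "F-repeated"
  nb <- adjacency$neighbours
  n_ch <- prep$n_ch
  n_sp <- prep$n_sp

  n_part <- n_partitions_of(prep)
  mode <- cfg$mode
  if (mode == "auto") {
    mode <- if (n_part <= cfg$exhaustive_cap) "exhaustive" else "monte-carlo"
  }
  if (mode == "monte-carlo" && n_part < 10) {
    stop_invalid(
      "only %d distinct partitions; monte-carlo refused, use exhaustive mode",
      n_part
    )
  }
  if (mode == "exhaustive" && n_part > cfg$exhaustive_cap) {
    stop_invalid(
      "exhaustive enumeration of %g partitions exceeds the cap %g",
      n_part, cfg$exhaustive_cap
    )
  }

  obs_clusters <- form_clusters_core(
    as.vector(map$stat), n_ch, n_sp, nb, thr,
    cfg$min_simultaneous_channels, signed
  )

  if (mode == "exhaustive") {
    parts <- enumerate_partitions(prep)
    null_dist <- vapply(parts, function(p) {
      max_cluster_mass(
        perm_stat(prep, p), n_ch, n_sp, nb, thr,
        cfg$min_simultaneous_channels, signed
      )
    }, numeric(1))
    denom <- length(parts)
    p_of <- function(mass) sum(null_dist >= abs(mass)) / denom
  } else {
    null_dist <- with_seed(cfg$seed, {
      vapply(seq_len(cfg$n_permutations), function(b) {
        max_cluster_mass(
          perm_stat(prep, random_partition(prep)), n_ch, n_sp, nb, thr,
          cfg$min_simultaneous_channels, signed
        )
      }, numeric(1))
    })
    denom <- cfg$n_permutations + 1L
    p_of <- function(mass) (1 + sum(null_dist >= abs(mass))) / denom
  }

  clusters <- cluster_tibble(obs_clusters, map)
  if (nrow(clusters)) {
    clusters$p_value <- vapply(clusters$mass, p_of, numeric(1))
    clusters$significant <- clusters$p_value <= cfg$alpha
    clusters$effect_size_d <- vapply(
      clusters$members,
      function(m) cluster_d_from_prep(prep, m$point), numeric(1)
    )
  } else {
    clusters$p_value <- numeric()
    clusters$significant <- logical()
    clusters$effect_size_d <- numeric()
  }

  structure(
    list(
      clusters = clusters, null_dist = null_dist, stat_map = map,
      config = cfg, mode = mode, n_partitions = n_part,
      threshold = thr, design = design, cond = cond,
      adjacency_info = list(
        criterion = adjacency$criterion,
        threshold = adjacency$threshold,
        mean_degree = adjacency$mean_degree
      )
    ),
    class = "cluster_result"
  )
}

# Cohen's d on per-subject scalars averaged over a cluster's member points
cluster_d_from_prep <- function(prep, points) {
  if (prep$design == "t-paired") {
    s <- rowMeans(prep$D[, points, drop = FALSE])
    if (sd(s) == 0) {
      return(sign(mean(s)) * Inf)
    }
    mean(s) / sd(s)
  } else if (prep$design == "t-independent") {
    s <- rowMeans(prep$X[, points, drop = FALSE])
    s1 <- s[prep$g1]
    s2 <- s[!prep$g1]
    sp <- sqrt(((length(s1) - 1) * var(s1) + (length(s2) - 1) * var(s2)) /
      (length(s1) + length(s2) - 2))
    if (sp == 0) {
      return(sign(mean(s1) - mean(s2)) * Inf)
    }
    (mean(s1) - mean(s2)) / sp
  } else {
    NA_real_ # d is defined for two-condition contrasts only
  }
}

#' Cluster-masked Cohen's d
#'
#' Averages each subject's voltage over a cluster's (channel, sample)
#' members and computes Cohen's d on the resulting scalars: paired d =
#' mean difference / SD of differences; independent d = mean difference /
#' pooled SD. Zero variance yields signed infinity.
#'
#' @inheritParams pointwise_stat
#' @param cluster One row of a cluster tibble (or a tibble with a `members`
#'   list-column entry) as returned by [form_clusters()] /
#'   [permutation_test()].
#' @return Signed Cohen's d.
#' @export
cluster_effect_size <- function(stack, cluster,
                                design = c("t-paired", "t-independent"),
                                cond = if (design[1] == "t-independent") "group" else "timepoint",
                                levels = NULL, subject = "subject") {
  design <- match.arg(design)
  members <- if (is.data.frame(cluster) && "members" %in% names(cluster)) {
    cluster$members[[1]]
  } else {
    cluster
  }
  if (is.null(members) || !nrow(members)) stop_invalid("cluster has no members")
  prep <- prepare_design(stack, design, cond, levels, subject)
  cluster_d_from_prep(prep, members$point)
}

#' Group-by-time interaction via difference-of-differences contrast
#'
#' Computes each subject's change waveform between two timepoints and runs
#' the independent-groups cluster permutation test on those differences:
#' a significant cluster indicates that the change from `times[1]` to
#' `times[2]` differs between the groups.
#'
#' @param stack An [erp_stack()] holding both groups at both timepoints.
#' @param times Length-2 character: the timepoints contrasted
#'   (difference = second minus first).
#' @param group_col,time_col,subject Metadata columns.
#' @param adjacency,cfg Passed to [permutation_test()].
#' @param groups Optional group level order (first minus second).
#' @return A `cluster_result` (design `"t-independent"` on change
#'   waveforms).
#' @export
interaction_contrast <- function(stack, times, group_col = "group",
                                 time_col = "timepoint", subject = "subject",
                                 groups = NULL, adjacency = NULL,
                                 cfg = stat_config()) {
  if (length(times) != 2L) stop_invalid("times must name two timepoints")
  info <- stack$info
  i1 <- which(info[[time_col]] == times[1])
  i2 <- which(info[[time_col]] == times[2])
  s1 <- info[[subject]][i1]
  s2 <- info[[subject]][i2]
  if (!setequal(s1, s2) || anyDuplicated(s1) || anyDuplicated(s2)) {
    stop_invalid("subjects must be matched across the two timepoints")
  }
  i2 <- i2[match(s1, s2)]
  diff_data <- stack$data[i2, , , drop = FALSE] - stack$data[i1, , , drop = FALSE]
  diff_info <- info[i1, , drop = FALSE]
  diff_info[[time_col]] <- paste0(times[2], "-", times[1])
  dstack <- erp_stack(diff_data, diff_info, stack$sfreq, stack$t_start, stack$montage)
  permutation_test(dstack,
    design = "t-independent", cond = group_col,
    levels = groups, subject = subject, adjacency = adjacency, cfg = cfg
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %s, %s mode, %d partitions of %g, threshold %.3f\n",
    x$design, x$mode,
    length(x$null_dist), x$n_partitions, x$threshold
  ))
  if (nrow(x$clusters)) {
    print(dplyr::select(x$clusters, -"members"), ...)
  } else {
    cat("  no suprathreshold clusters\n")
  }
  invisible(x)
}
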