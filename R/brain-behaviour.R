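#' Area under the curve of an ERP over a cluster
#'
#' Averages the ERP across the cluster's channel set and integrates the
#' resulting waveform over the cluster's time extent with the trapezoid rule,
#' giving a signed area in microvolt-milliseconds. By default the cluster's
#' rectangular hull is used (all member channels over the full member time
#' extent); `member_exact = TRUE` instead averages, at each time sample, only
#' the channels that are cluster members at that sample.
#'
#' @param stack An [erp_stack()] (each observation yields one AUC) or a
#'   single channels x samples matrix with matching timing.
#' @param cluster One row of a cluster tibble (with a `members` list-column)
#'   or the member tibble itself.
#' @param member_exact Use the member-exact mask instead of the hull.
#' @param times_ms Sample times in ms; required only for matrix input.
#' @return For an `erp_stack`: tibble with the stack metadata plus
#'   `auc_uv_ms`. For a matrix: a single number.
#' @export
cluster_auc <- function(stack, cluster, member_exact = FALSE, times_ms = NULL) {
  members <- if (is.data.frame(cluster) && "members" %in% names(cluster)) {
    cluster$members[[1]]
  } else {
    cluster
  }
  if (!nrow(members)) stop_invalid("cluster has no members")

  auc_one <- function(mat, times_ms) {
    if (max(members$sample) > ncol(mat)) {
      stop_invalid("cluster window lies outside the ERP")
    }
    smp <- sort(unique(members$sample))
    if (member_exact) {
      wave <- vapply(smp, function(s) {
        mean(mat[members$channel_idx[members$sample == s], s])
      }, numeric(1))
    } else {
      ch <- sort(unique(members$channel_idx))
      wave <- colMeans(mat[ch, smp, drop = FALSE])
    }
    if (length(smp) < 2L) {
      return(0)
    }
    pracma::trapz(times_ms[smp], wave)
  }

  if (is.matrix(stack)) {
    if (is.null(times_ms)) stop_invalid("matrix input requires times_ms")
    return(auc_one(stack, times_ms))
  }
  times_ms <- stack_times(stack) * 1000
  n <- dim(stack$data)[1]
  auc <- vapply(seq_len(n), function(i) {
    auc_one(stack$data[i, , , drop = FALSE][1, , ], times_ms)
  }, numeric(1))
  dplyr::mutate(stack$info, auc_uv_ms = auc)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Correlates a cluster AUC (or any brain measure) with a behavioural
#' measure across matched subject x timepoint observations. Rows with
#' missing values in either variable are dropped and the reported `n`
#' reflects that; degrees of freedom are `n - 2`.
#'
#' @param data Tibble holding both variables.
#' @param x,y Column names (strings) of the two variables.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return One-row tibble: `r`, `n`, `df`, `p_value`, `conf_low`,
#'   `conf_high`.
#' @export
correlate <- function(data, x, y, conf_level = 0.95) {
  xv <- data[[x]]
  yv <- data[[y]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3L) stop_invalid("need >= 3 matched pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("correlation undefined: zero variance in one variable",
      class = "erpcluster_undefined_correlation"
    )
  }
  ct <- cor.test(xv, yv, conf.level = conf_level)
  has_ci <- !is.null(ct$conf.int) # Fisher-z CI needs n >= 4
  tibble::tibble(
    r = unname(ct$estimate), n = length(xv), df = length(xv) - 2L,
    p_value = ct$p.value,
    conf_low = if (has_ci) ct$conf.int[1] else NA_real_,
    conf_high = if (has_ci) ct$conf.int[2] else NA_real_
  )
}

#' Brain-behaviour correlation over pooled timepoints
#'
#' For each group, pools the per-subject cluster AUC values across
#' timepoints and correlates them with the matched behavioural outcome
#' (target reaction time by default). An optional 5th-95th percentile
#' outlier screen is applied to both variables before correlating, with
#' exclusions logged in the output; per-timepoint correlations are also
#' returned.
#'
#' @param auc_tbl Tibble from [cluster_auc()]: `subject`, `group`,
#'   `timepoint`, `auc_uv_ms`.
#' @param behaviour Tibble with `subject`, `timepoint` and the outcome
#'   column.
#' @param outcome Behavioural column name (default `"rt_mean_ms"`).
#' @param outlier_screen Apply [percentile_outliers()] to both variables.
#' @return List with `pooled` (one row per group: correlation results plus
#'   `n_excluded`) and `per_timepoint` (one row per group x timepoint).
#' @export
correlate_brain_behaviour <- function(auc_tbl, behaviour,
                                      outcome = "rt_mean_ms",
                                      outlier_screen = TRUE) {
  joined <- dplyr::inner_join(
    auc_tbl, behaviour,
    by = intersect(
      c("subject", "group", "timepoint"),
      intersect(names(auc_tbl), names(behaviour))
    )
  )
  one <- function(d) {
    excl <- rep(FALSE, nrow(d))
    if (outlier_screen && nrow(d) >= 10) {
      excl <- percentile_outliers(d$auc_uv_ms)$flag |
        percentile_outliers(d[[outcome]])$flag
    }
    res <- correlate(d[!excl, , drop = FALSE], "auc_uv_ms", outcome)
    dplyr::mutate(res, n_excluded = sum(excl))
  }
  pooled <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  per_tp <- joined |>
    dplyr::group_by(.data$group, .data$timepoint) |>
    dplyr::group_modify(~ tryCatch(one(.x), error = function(e) tibble::tibble())) |>
    dplyr::ungroup()
  list(pooled = pooled, per_timepoint = per_tp)
}
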