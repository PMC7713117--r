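#' Reaction-time coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean;
#' dimensionless. Indexes the stability of sustained attention: larger
#' values mean more variable responding.
#'
#' @param rts Numeric vector of reaction times (>= 2 values, positive mean).
#' @return SD/mean.
#' @examples
#' rtcv(c(300, 500)) # 0.3536
#' @export
rtcv <- function(rts) {
  if (length(rts) < 2L) stop_invalid("rtcv needs >= 2 values")
  m <- mean(rts)
  if (m <= 0) stop_invalid("rtcv needs a positive mean")
  sd(rts) / m
}

#' AX-CPT error rate
#'
#' Total errors (misses on AX targets plus false alarms on non-targets) as a
#' percentage of all trials in the block.
#'
#' @param errors Error count, or a logical vector of per-trial error flags.
#' @param n_trials Total trials (taken from the vector length if omitted).
#' @return Percentage in [0, 100].
#' @export
error_rate <- function(errors, n_trials = NULL) {
  if (is.logical(errors)) {
    if (is.null(n_trials)) n_trials <- length(errors)
    errors <- sum(errors)
  }
  if (is.null(n_trials) || n_trials < 1) stop_invalid("need >= 1 trial")
  100 * errors / n_trials
}

#' Breath-counting accuracy
#'
#' Percentage of correctly completed count cycles out of all cycles
#' attempted; self-caught errors count as incorrect cycles.
#'
#' @param correct Correct cycle count, or per-cycle outcome vector with
#'   values `"correct"`, `"incorrect"`, `"self_caught"`.
#' @param total Total attempted cycles (from the vector if omitted).
#' @return Percentage in [0, 100].
#' @examples
#' breath_accuracy(15, 20) # 75
#' @export
breath_accuracy <- function(correct, total = NULL) {
  if (is.character(correct) || is.factor(correct)) {
    outcomes <- as.character(correct)
    if (is.null(total)) total <- length(outcomes)
    correct <- sum(outcomes == "correct")
  }
  if (is.null(total) || total < 1) stop_invalid("need >= 1 cycle")
  100 * correct / total
}

hedges_g <- function(d, df) d * (1 - 3 / (4 * df - 1))

#' Pooled-variance independent-groups t test
#'
#' Accepts either raw values or printed summary statistics (mean, SD, n) for
#' each group, and reproduces published t values from summary tables
#' exactly. Degrees of freedom are n1 + n2 - 2 (pooled variance, not
#' Welch). Hedges' g applies the small-sample correction
#' g = d (1 - 3 / (4 df - 1)).
#'
#' @param x,y Numeric vectors of raw values, or lists/named vectors with
#'   `mean`, `sd`, `n`.
#' @param label Comparison label carried into the output.
#' @return One-row tibble: `comparison`, `t`, `df`, `p_value`, `hedges_g`,
#'   `cohens_d`.
#' @examples
#' independent_t(
#'   list(mean = 44.8, sd = 32.7, n = 50),
#'   list(mean = 53.4, sd = 34.8, n = 31)
#' )
#' @export
independent_t <- function(x, y, label = "group1 vs group2") {
  as_summ <- function(v) {
    if (is.list(v) || !is.null(names(v))) {
      list(mean = v[["mean"]], sd = v[["sd"]], n = v[["n"]])
    } else {
      if (length(v) < 2L) stop_invalid("each group needs >= 2 values")
      list(mean = mean(v), sd = sd(v), n = length(v))
    }
  }
  a <- as_summ(x)
  b <- as_summ(y)
  if (a$n < 2 || b$n < 2) stop_invalid("each group needs n >= 2")
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 <= 0) {
    if (a$mean == b$mean) { # fully degenerate: no spread, no difference
      return(tibble::tibble(
        comparison = label, t = 0, df = df, p_value = 1,
        cohens_d = 0, hedges_g = 0
      ))
    }
    abort("pooled variance is zero with a nonzero mean difference; t undefined",
      class = "erpcluster_undefined_statistic"
    )
  }
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  t <- (a$mean - b$mean) / se
  d <- (a$mean - b$mean) / sqrt(sp2)
  tibble::tibble(
    comparison = label, t = t, df = df,
    p_value = 2 * pt(-abs(t), df),
    cohens_d = d, hedges_g = hedges_g(d, df)
  )
}

#' Paired t test with Hedges' g
#'
#' t on within-subject differences (df = n - 1); Hedges' g on the
#' differences with the small-sample correction.
#'
#' @param x,y Matched numeric vectors (difference = x - y), or `y = NULL`
#'   with `x` already the differences.
#' @param label Comparison label.
#' @return One-row tibble: `comparison`, `t`, `df`, `p_value`, `hedges_g`,
#'   `cohens_d`.
#' @export
paired_t <- function(x, y = NULL, label = "paired") {
  d <- if (is.null(y)) x else x - y
  if (length(d) < 2L) stop_invalid("need >= 2 matched pairs")
  if (sd(d) == 0) {
    if (mean(d) == 0) { # identical conditions: a null result, not an error
      return(tibble::tibble(
        comparison = label, t = 0, df = length(d) - 1L, p_value = 1,
        cohens_d = 0, hedges_g = 0
      ))
    }
    abort("zero difference variance with a nonzero mean difference; t undefined",
      class = "erpcluster_undefined_statistic"
    )
  }
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  dd <- mean(d) / sd(d)
  tibble::tibble(
    comparison = label, t = t, df = n - 1L,
    p_value = 2 * pt(-abs(t), n - 1),
    cohens_d = dd, hedges_g = hedges_g(dd, n - 1)
  )
}

#' Mixed (split-plot) ANOVA: between-groups factor x within-subject time
#'
#' Classical two-way mixed ANOVA with one between-groups factor and one
#' within-subject factor, fitted with `stats::aov` using an
#' `Error(subject)` stratum. Reports F, degrees of freedom, p and partial
#' eta squared for the group, time and group x time effects, plus
#' d = 2 sqrt(eta2 / (1 - eta2)) as a labelled convenience conversion
#' (non-authoritative). Subjects missing any timepoint are dropped with a
#' logged count.
#'
#' @param data Tibble with `subject`, `group`, `timepoint` and the outcome.
#' @param dv Outcome column name.
#' @return An object of class `mixed_anova`; `tidy()` gives one row per
#'   effect, `glance()` the fit bookkeeping.
#' @export
mixed_anova <- function(data, dv) {
  if (!dv %in% names(data)) stop_invalid("outcome column '%s' missing", dv)
  tps <- unique(as.character(data$timepoint))
  complete <- data |>
    dplyr::filter(is.finite(.data[[dv]])) |>
    dplyr::group_by(.data$subject) |>
    dplyr::filter(dplyr::n_distinct(.data$timepoint) == length(tps)) |>
    dplyr::ungroup()
  n_dropped <- dplyr::n_distinct(data$subject) -
    dplyr::n_distinct(complete$subject)
  if (dplyr::n_distinct(complete$subject) < 4) {
    stop_invalid("too few complete subjects for the mixed ANOVA")
  }
  df <- data.frame(
    subject = factor(complete$subject),
    group = factor(complete$group),
    time = factor(complete$timepoint),
    y = complete[[dv]]
  )
  one_group <- nlevels(df$group) < 2L
  fit <- if (one_group) {
    aov(y ~ time + Error(subject), data = df)
  } else {
    aov(y ~ group * time + Error(subject), data = df)
  }
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  rn <- function(tab) trimws(rownames(tab))
  # relative tolerance against floating-point dust in degenerate tables
  ss_tol <- 1e-10 * max(sum(df$y^2), 1e-300)
  pick <- function(tab, term, err_row) {
    i <- match(term, rn(tab))
    ss <- tab[i, "Sum Sq"]
    ss_err <- tab[err_row, "Sum Sq"]
    fval <- tab[i, "F value"]
    pval <- tab[i, "Pr(>F)"]
    # no variance anywhere in the stratum: report a null effect, not noise
    if (ss <= ss_tol && ss_err <= ss_tol) {
      ss <- 0
      ss_err <- 0
      fval <- 0
      pval <- 1
    }
    eta2 <- if (ss + ss_err > 0) ss / (ss + ss_err) else 0
    tibble::tibble(
      effect = c(
        "group" = "group", "time" = "time",
        "group:time" = "group x time"
      )[term],
      F = fval, df1 = tab[i, "Df"], df2 = tab[err_row, "Df"],
      p_value = pval, partial_eta2 = eta2,
      d_equiv = 2 * sqrt(eta2 / (1 - eta2))
    )
  }
  res <- if (one_group) {
    pick(within, "time", match("Residuals", rn(within)))
  } else {
    dplyr::bind_rows(
      pick(between, "group", match("Residuals", rn(between))),
      pick(within, "time", match("Residuals", rn(within))),
      pick(within, "group:time", match("Residuals", rn(within)))
    )
  }
  structure(
    list(
      table = res, dv = dv,
      n_subjects = dplyr::n_distinct(complete$subject),
      n_dropped = n_dropped, fit = fit
    ),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf(
    "Mixed ANOVA on '%s' (%d subjects, %d dropped)\n",
    x$dv, x$n_subjects, x$n_dropped
  ))
  print(x$table, ...)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up procedure at level `q`: sorted p-values are compared against
#' `(i / m) q` and all hypotheses up to the largest passing index are
#' rejected. Adjusted values come from `stats::p.adjust(method = "BH")` and
#' are monotone non-decreasing in the sorted order.
#'
#' @param pvals P-values in [0, 1].
#' @param q FDR level.
#' @return Tibble: `p_value`, `p_adjusted`, `rejected` (input order).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  adj <- p.adjust(pvals, method = "BH")
  ord <- order(pvals)
  passing <- which(pvals[ord] <= q * seq_len(m) / m)
  rejected <- logical(m)
  if (length(passing)) rejected[ord[seq_len(max(passing))]] <- TRUE
  tibble::tibble(p_value = pvals, p_adjusted = adj, rejected = rejected)
}

#' Two-tailed percentile outlier screen
#'
#' Flags values strictly below the `lo`th or strictly above the `hi`th
#' percentile (type-7 linear-interpolation percentiles, the R default).
#' With fewer than 10 values nothing is flagged and a warning is issued.
#'
#' @param values Numeric vector.
#' @param lo,hi Percentile bounds (defaults 5 and 95).
#' @return List with `flag` (logical mask), `bounds`, and `n_flagged`.
#' @export
percentile_outliers <- function(values, lo = 5, hi = 95) {
  if (length(values) < 10L) {
    warn("fewer than 10 values; outlier screen skipped")
    return(list(
      flag = rep(FALSE, length(values)),
      bounds = c(NA_real_, NA_real_), n_flagged = 0L
    ))
  }
  b <- quantile(values, c(lo, hi) / 100, type = 7, names = FALSE)
  flag <- values < b[1] | values > b[2]
  list(flag = flag, bounds = b, n_flagged = sum(flag))
}
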