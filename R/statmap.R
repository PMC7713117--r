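# sentinel statistic for zero-variance points with a genuine mean difference:
# large, finite, sign-preserving, so degenerate inputs behave like a maximal
# effect without producing NaN/Inf arithmetic downstream
BIG_STAT <- 1e9

# ---- vectorised pointwise statistics over flattened (obs x points) data ----

# pooled-variance independent t at every point; g1 = logical group-1 selector
t_independent_vec <- function(X, X2, g1) {
  n1 <- sum(g1)
  n2 <- length(g1) - n1
  s1 <- colSums(X[g1, , drop = FALSE])
  s2 <- colSums(X) - s1
  q1 <- colSums(X2[g1, , drop = FALSE])
  q2 <- colSums(X2) - q1
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- pmax(q1 - n1 * m1^2, 0)
  v2 <- pmax(q2 - n2 * m2^2, 0)
  vp <- (v1 + v2) / (n1 + n2 - 2)
  md <- m1 - m2
  se <- sqrt(vp * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, md / se, ifelse(md == 0, 0, sign(md) * BIG_STAT))
  t
}

# paired / one-sample t on difference rows, under sign flips eps (+/-1)
t_paired_vec <- function(D, cs2, eps) {
  n <- nrow(D)
  m <- as.vector(crossprod(eps, D)) / n
  v <- pmax(cs2 - n * m^2, 0) / (n - 1)
  se <- sqrt(v / n)
  ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * BIG_STAT))
}

# one-way repeated-measures F; Xs = list of k (n x P) condition matrices,
# assign = n x k matrix: condition j of subject i takes original condition
# assign[i, j]. ss_within_total and subject means are permutation-invariant.
# ss_tol guards the degenerate (zero within-subject variance) branch against
# floating-point dust in the sums of squares.
f_repeated_vec <- function(Xs, assign, ss_within_total, ss_tol = 0) {
  k <- length(Xs)
  n <- nrow(Xs[[1]])
  P <- ncol(Xs[[1]])
  ss_cond <- numeric(P)
  G <- numeric(P)
  Cs <- vector("list", k)
  for (j in seq_len(k)) {
    acc <- numeric(P)
    for (i in seq_len(n)) {
      acc <- acc + Xs[[assign[i, j]]][i, ]
    }
    Cs[[j]] <- acc / n
    G <- G + Cs[[j]] / k
  }
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (Cs[[j]] - G)^2
  ss_err <- pmax(ss_within_total - ss_cond, 0)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- ifelse(ss_err > ss_tol, (ss_cond / df1) / (ss_err / df2),
    ifelse(ss_cond <= ss_tol, 0, BIG_STAT)
  )
  f
}

# ---- design preparation -----------------------------------------------------

flatten_stack <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, d[1], d[2] * d[3]) # point index = ch + (s-1)*n_ch
}

# build the internal representation a permutation engine needs
prepare_design <- function(stack, design, cond, levels = NULL,
                           subject = "subject") {
  info <- stack$info
  if (!cond %in% names(info)) stop_invalid("condition column '%s' missing", cond)
  vals <- as.character(info[[cond]])
  if (is.null(levels)) levels <- unique(vals)
  d <- dim(stack$data)
  n_ch <- d[2]
  n_sp <- d[3]
  X_all <- flatten_stack(stack)

  if (design == "t-independent") {
    if (length(levels) != 2L) stop_invalid("t-independent needs 2 levels")
    keep <- vals %in% levels
    X <- X_all[keep, , drop = FALSE]
    g1 <- vals[keep] == levels[1]
    if (sum(g1) < 2L || sum(!g1) < 2L) {
      stop_invalid("need >= 2 subjects per group")
    }
    list(
      design = design, X = X, X2 = X^2, g1 = g1,
      n = nrow(X), n1 = sum(g1), df = nrow(X) - 2L,
      kind = "t-independent", n_ch = n_ch, n_sp = n_sp
    )
  } else if (design == "t-paired") {
    if (length(levels) != 2L) stop_invalid("t-paired needs 2 levels")
    i1 <- which(vals == levels[1])
    i2 <- which(vals == levels[2])
    s1 <- info[[subject]][i1]
    s2 <- info[[subject]][i2]
    if (length(i1) != length(i2) || !setequal(s1, s2) ||
      anyDuplicated(s1) || anyDuplicated(s2)) {
      stop_invalid("paired design needs matched subject sets in both conditions")
    }
    i2 <- i2[match(s1, s2)]
    if (length(i1) < 2L) stop_invalid("need >= 2 matched subjects")
    D <- X_all[i1, , drop = FALSE] - X_all[i2, , drop = FALSE]
    list(
      design = design, D = D, cs2 = colSums(D^2),
      n = nrow(D), df = nrow(D) - 1L,
      kind = "t-paired", n_ch = n_ch, n_sp = n_sp
    )
  } else if (design == "F-repeated") {
    if (length(levels) < 3L) stop_invalid("F-repeated needs >= 3 levels")
    k <- length(levels)
    idx <- lapply(levels, function(l) which(vals == l))
    subs <- lapply(idx, function(i) info[[subject]][i])
    for (j in seq_len(k)) {
      if (!setequal(subs[[j]], subs[[1]]) || anyDuplicated(subs[[j]])) {
        stop_invalid("F-repeated design needs matched subject sets across levels")
      }
      idx[[j]] <- idx[[j]][match(subs[[1]], subs[[j]])]
    }
    if (length(idx[[1]]) < 2L) stop_invalid("need >= 2 matched subjects")
    Xs <- lapply(idx, function(i) X_all[i, , drop = FALSE])
    n <- nrow(Xs[[1]])
    S <- Reduce(`+`, Xs) / k # subject means, invariant
    sq_total <- Reduce(`+`, lapply(Xs, function(x) colSums(x^2)))
    ss_within_total <- pmax(sq_total - k * colSums(S^2), 0)
    list(
      design = design, Xs = Xs, ss_within_total = ss_within_total,
      ss_tol = 1e-12 * pmax(sq_total, 1e-300),
      n = n, k = k, df = c(k - 1L, (n - 1L) * (k - 1L)),
      kind = "F-repeated", n_ch = n_ch, n_sp = n_sp
    )
  } else {
    stop_invalid("unknown design '%s'", design)
  }
}

observed_stat <- function(prep) {
  switch(prep$design,
    "t-independent" = t_independent_vec(prep$X, prep$X2, prep$g1),
    "t-paired" = t_paired_vec(prep$D, prep$cs2, rep(1, prep$n)),
    "F-repeated" = f_repeated_vec(
      prep$Xs, matrix(rep(seq_len(prep$k), each = prep$n), prep$n),
      prep$ss_within_total, prep$ss_tol
    )
  )
}

#' Pointwise statistic map over channels and time
#'
#' Computes, independently at every (channel, sample) point, the test
#' statistic of the requested design: pooled-variance independent-groups t,
#' paired t across two matched conditions, or one-way repeated-measures F
#' across three or more matched conditions. Points with zero variance are
#' flagged and assigned 0 when the mean difference is also zero, or a large
#' finite sign-preserving sentinel otherwise.
#'
#' @param stack An [erp_stack()] with one row per subject x condition.
#' @param design `"t-independent"`, `"t-paired"` or `"F-repeated"`.
#' @param cond Metadata column defining the conditions.
#' @param levels Condition levels; order fixes the contrast direction
#'   (first minus second). Default: order of appearance.
#' @param subject Metadata column identifying subjects (matched designs).
#' @return A `stat_map`: list with `stat` (channels x samples matrix),
#'   `kind`, `df`, `sfreq`, `t_start`, `montage`, `n_degenerate` (count of
#'   zero-variance points).
#' @export
pointwise_stat <- function(stack, design = c(
                             "t-independent", "t-paired",
                             "F-repeated"
                           ),
                           cond = "group", levels = NULL,
                           subject = "subject") {
  design <- match.arg(design)
  prep <- prepare_design(stack, design, cond, levels, subject)
  stat <- observed_stat(prep)
  structure(
    list(
      stat = matrix(stat, prep$n_ch, prep$n_sp,
        dimnames = list(stack$montage$channels$channel, NULL)
      ),
      kind = prep$kind, df = prep$df,
      sfreq = stack$sfreq, t_start = stack$t_start, montage = stack$montage,
      n_degenerate = sum(abs(stat) >= BIG_STAT)
    ),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "<stat_map> %s, df = %s, %d channels x %d samples, max |stat| = %.3g\n",
    x$kind, paste(x$df, collapse = ","), nrow(x$stat), ncol(x$stat),
    max(abs(x$stat))
  ))
  invisible(x)
}
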