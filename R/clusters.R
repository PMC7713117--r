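# ---- spatiotemporal cluster forming ----------------------------------------
#
# Points are indexed channel-major: point = ch + (s - 1) * n_ch. Two
# suprathreshold points of like sign are connected when they share a channel
# and sit at adjacent samples, or share a sample and sit at adjacent channels
# (sensor adjacency graph). After labelling, any time-slice of a cluster with
# fewer than `min_chan` simultaneous channels is pruned; surviving members
# define the cluster mass (sum of the statistic over members).

# core labelling; stat is a vector of length n_ch * n_sp.
# Returns list of clusters: each list(members, mass, sign).
form_clusters_core <- function(stat, n_ch, n_sp, neighbours, threshold,
                               min_chan, signed = TRUE) {
  if (signed) {
    idx <- which(stat > threshold | stat < -threshold)
  } else {
    idx <- which(stat > threshold)
  }
  if (!length(idx)) {
    return(list())
  }
  sgn <- if (signed) sign(stat[idx]) else rep(1, length(idx))
  pos <- integer(n_ch * n_sp)
  pos[idx] <- seq_along(idx)

  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in seq_along(idx)) {
    p <- idx[j]
    ch <- (p - 1L) %% n_ch + 1L
    # temporal neighbour: same channel, previous sample
    if (p > n_ch) {
      q <- pos[p - n_ch]
      if (q > 0L && sgn[q] == sgn[j]) {
        a <- find(j)
        b <- find(q)
        if (a != b) parent[a] <- b
      }
    }
    # spatial neighbours at the same sample, smaller channel index
    for (cn in neighbours[[ch]]) {
      if (cn < ch) {
        q <- pos[p - ch + cn]
        if (q > 0L && sgn[q] == sgn[j]) {
          a <- find(j)
          b <- find(q)
          if (a != b) parent[a] <- b
        }
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  groups <- split(seq_along(idx), roots)

  out <- list()
  for (g in groups) {
    members <- idx[g]
    if (min_chan > 1L) {
      smp <- (members - 1L) %/% n_ch + 1L
      cnt <- tabulate(smp, nbins = n_sp)
      members <- members[cnt[smp] >= min_chan]
      if (!length(members)) next
    }
    out[[length(out) + 1L]] <- list(
      members = members,
      mass = sum(stat[members]),
      sign = if (signed) sign(stat[members[1]]) else 1
    )
  }
  out
}

# largest |mass| over clusters; 0 when none survive
max_cluster_mass <- function(stat, n_ch, n_sp, neighbours, threshold,
                             min_chan, signed = TRUE) {
  cl <- form_clusters_core(stat, n_ch, n_sp, neighbours, threshold, min_chan,
    signed = signed
  )
  if (!length(cl)) {
    return(0)
  }
  max(abs(vapply(cl, `[[`, numeric(1), "mass")))
}

#' Form spatiotemporal clusters from a statistic map
#'
#' Groups suprathreshold points of like sign by spatiotemporal connectivity
#' (same channel at adjacent samples, or sensor-adjacent channels at the same
#' sample), prunes any time-slice of a cluster with fewer than
#' `cfg$min_simultaneous_channels` simultaneous channels, and sums the
#' statistic over the surviving members to give each cluster's mass.
#' The cluster-forming threshold is the pointwise critical value of the
#' map's statistic at the configured cluster-forming alpha (two-tailed for t,
#' upper tail for F).
#'
#' @param map A `stat_map` from [pointwise_stat()].
#' @param adjacency An `adjacency` from [build_adjacency()]; `NULL` builds
#'   the default for the map's montage.
#' @param cfg A [stat_config()].
#' @return A tibble with one row per cluster: `cluster_id`, `sign`, `mass`,
#'   `t_start_ms`, `t_end_ms`, `n_channels`, `n_points`, plus a `members`
#'   list-column of tibbles (`channel`, `sample`, `time_ms`, `stat`).
#'   Empty (0-row) when nothing is suprathreshold.
#' @export
form_clusters <- function(map, adjacency = NULL, cfg = stat_config()) {
  if (is.null(adjacency)) adjacency <- build_adjacency(map$montage)
  thr <- cluster_forming_threshold(map, cfg)
  signed <- map$kind != "F-repeated"
  n_ch <- nrow(map$stat)
  n_sp <- ncol(map$stat)
  cl <- form_clusters_core(
    as.vector(map$stat), n_ch, n_sp, adjacency$neighbours,
    thr, cfg$min_simultaneous_channels,
    signed = signed
  )
  cluster_tibble(cl, map)
}

cluster_forming_threshold <- function(map, cfg) {
  ca <- cfg$cluster_alpha %||% cfg$alpha
  if (map$kind == "F-repeated") {
    qf(1 - ca, map$df[1], map$df[2])
  } else {
    qt(1 - ca / 2, map$df)
  }
}

cluster_tibble <- function(cl, map) {
  n_ch <- nrow(map$stat)
  times_ms <- sample_times(ncol(map$stat), map$sfreq, map$t_start) * 1000
  labels <- map$montage$channels$channel
  if (!length(cl)) {
    return(tibble::tibble(
      cluster_id = integer(), sign = numeric(), mass = numeric(),
      t_start_ms = numeric(), t_end_ms = numeric(),
      n_channels = integer(), n_points = integer(),
      members = list()
    ))
  }
  rows <- lapply(seq_along(cl), function(i) {
    c0 <- cl[[i]]
    ch <- (c0$members - 1L) %% n_ch + 1L
    smp <- (c0$members - 1L) %/% n_ch + 1L
    tibble::tibble(
      cluster_id = i, sign = c0$sign, mass = c0$mass,
      t_start_ms = min(times_ms[smp]), t_end_ms = max(times_ms[smp]),
      n_channels = length(unique(ch)), n_points = length(c0$members),
      members = list(tibble::tibble(
        channel = labels[ch], channel_idx = ch, sample = smp,
        time_ms = times_ms[smp], stat = as.vector(map$stat)[c0$members],
        point = c0$members
      ))
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-abs(out$mass)), ] |>
    dplyr::mutate(cluster_id = dplyr::row_number())
}
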