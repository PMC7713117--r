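#' Build a deterministic sensor montage
#'
#' Creates a schematic EEG sensor layout. Three built-in layouts are provided:
#' `"ring"` (equally spaced points on a circle with unit spacing between
#' neighbours; for fewer than 4 channels the ring degenerates to a line with
#' unit spacing), `"grid"` (near-square lattice, unit spacing) and
#' `"reduced-head"` (sunflower-spiral layout inside a schematic head disc of
#' 10 cm radius, a stand-in for a high-density scalp net at desk scale).
#' Coordinates are deterministic: the same inputs always give the identical
#' montage.
#'
#' @param n_channels Number of channels (>= 2).
#' @param layout One of `"ring"`, `"grid"`, `"reduced-head"`.
#' @return A `montage` object: list with `channels` (a tibble with columns
#'   `channel`, `x`, `y`) and `layout`.
#' @examples
#' make_montage(32, "reduced-head")
#' @export
make_montage <- function(n_channels, layout = c("reduced-head", "ring", "grid")) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 2) {
    stop_invalid("n_channels must be a single integer >= 2")
  }
  n <- as.integer(n_channels)
  layout <- tryCatch(match.arg(layout),
    error = function(e) stop_invalid("unknown layout '%s'", layout[1])
  )
  pos <- switch(layout,
    "ring" = {
      if (n < 4L) {
        cbind(x = seq_len(n) - 1, y = rep(0, n))
      } else {
        r <- 1 / (2 * sin(pi / n)) # unit chord spacing
        th <- 2 * pi * (seq_len(n) - 1) / n
        cbind(x = r * cos(th), y = r * sin(th))
      }
    },
    "grid" = {
      ncol_ <- ceiling(sqrt(n))
      i <- seq_len(n) - 1L
      cbind(x = i %% ncol_, y = i %/% ncol_)
    },
    "reduced-head" = {
      # Vogel sunflower spiral: uniform coverage of the head disc
      head_r <- 0.1 # metres
      i <- seq_len(n)
      r <- head_r * sqrt((i - 0.5) / n)
      th <- i * 2.399963229728653 # golden angle
      cbind(x = r * cos(th), y = r * sin(th))
    }
  )
  ch <- tibble::tibble(
    channel = sprintf("E%03d", seq_len(n)),
    x = as.numeric(pos[, "x"]),
    y = as.numeric(pos[, "y"])
  )
  structure(list(channels = ch, layout = layout), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf(
    "<montage> %d channels, layout '%s'\n",
    nrow(x$channels), x$layout
  ))
  invisible(x)
}

montage_positions <- function(montage) {
  as.matrix(montage$channels[, c("x", "y")])
}

validate_montage <- function(montage) {
  ch <- montage$channels
  if (nrow(ch) < 2L) stop_invalid("montage needs >= 2 channels")
  if (anyDuplicated(ch$channel)) stop_invalid("montage labels must be unique")
  if (!all(is.finite(ch$x)) || !all(is.finite(ch$y))) {
    stop_invalid("montage coordinates must be finite")
  }
  invisible(montage)
}

#' Read / write a plain-text montage file
#'
#' One line per channel, whitespace-separated: `label x y [z]`; `#` starts a
#' comment. The optional z coordinate is kept if present.
#'
#' @param path File path.
#' @return `read_montage()` returns a `montage`; `write_montage()` returns
#'   `path` invisibly.
#' @export
read_montage <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  bad <- vapply(parts, function(p) length(p) < 3L, logical(1))
  if (any(bad)) stop_invalid("montage file lines need 'label x y [z]'")
  ch <- tibble::tibble(
    channel = vapply(parts, `[[`, character(1), 1L),
    x = as.numeric(vapply(parts, `[[`, character(1), 2L)),
    y = as.numeric(vapply(parts, `[[`, character(1), 3L))
  )
  m <- structure(list(channels = ch, layout = "file"), class = "montage")
  validate_montage(m)
}

#' @rdname read_montage
#' @param montage A `montage` object.
#' @export
write_montage <- function(montage, path) {
  validate_montage(montage)
  lines <- sprintf(
    "%s %.9g %.9g",
    montage$channels$channel, montage$channels$x, montage$channels$y
  )
  writeLines(c("# montage: label x y", lines), path)
  invisible(path)
}

#' Build a channel adjacency graph from sensor positions
#'
#' Two channels are neighbours when their Euclidean distance is at most a
#' threshold (`criterion = "distance"`), or when either is among the other's
#' k nearest sensors (`criterion = "knn"`, symmetrised). The default
#' `threshold = NULL` picks the distance cutoff whose resulting mean degree is
#' closest to `target_degree` (about 6, a typical sensor-net neighbourhood
#' size); the chosen criterion and threshold are recorded on the result.
#'
#' @param montage A `montage`.
#' @param criterion `"distance"` or `"knn"`.
#' @param threshold Distance cutoff (criterion `"distance"`) or k
#'   (criterion `"knn"`). `NULL` = automatic.
#' @param target_degree Mean degree aimed for by the automatic threshold.
#' @return An `adjacency` object: list with `matrix` (logical, symmetric, no
#'   self-edges), `neighbours` (list of integer vectors), `criterion`,
#'   `threshold`, `mean_degree`.
#' @export
build_adjacency <- function(montage, criterion = c("distance", "knn"),
                            threshold = NULL, target_degree = 6) {
  validate_montage(montage)
  criterion <- match.arg(criterion)
  pos <- montage_positions(montage)
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  if (criterion == "distance") {
    if (is.null(threshold)) {
      cand <- sort(unique(d[upper.tri(d)]))
      deg <- vapply(cand, function(th) mean(rowSums(d <= th) - 1), numeric(1))
      threshold <- cand[which.min(abs(deg - target_degree))]
    }
    adj <- d <= threshold
  } else {
    if (is.null(threshold)) threshold <- max(2L, round(target_degree / 2))
    k <- as.integer(threshold)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:min(n, k + 1L)]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj) # symmetrise
  }
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$channels$channel, montage$channels$channel)
  deg <- rowSums(adj)
  if (any(deg == 0)) {
    warn(sprintf(
      "%d isolated channel(s) in adjacency graph; clusters can still extend over time",
      sum(deg == 0)
    ))
  }
  structure(
    list(
      matrix = adj,
      neighbours = apply(adj, 1L, which, simplify = FALSE),
      criterion = criterion,
      threshold = threshold,
      mean_degree = mean(deg)
    ),
    class = "adjacency"
  )
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf(
    "<adjacency> %d channels, criterion '%s' (threshold %.4g), mean degree %.2f\n",
    nrow(x$matrix), x$criterion, x$threshold, x$mean_degree
  ))
  invisible(x)
}

# map a verbal scalp region to schematic head coordinates (+y anterior,
# +x right, head radius taken from the montage extent)
region_coords <- function(region, montage) {
  pos <- montage_positions(montage)
  r <- max(sqrt(rowSums(pos^2)))
  regions <- list(
    "left-parieto-occipital"  = c(-0.55, -0.60),
    "right-parieto-occipital" = c(0.55, -0.60),
    "parietal-temporal"       = c(-0.70, -0.25),
    "occipital"               = c(0.00, -0.85),
    "centroparietal"          = c(0.00, -0.30),
    "frontocentral"           = c(0.00, 0.35),
    "vertex"                  = c(0.00, 0.00)
  )
  if (!region %in% names(regions)) {
    stop_invalid(
      "unknown scalp region '%s' (known: %s)",
      region, paste(names(regions), collapse = ", ")
    )
  }
  regions[[region]] * r
}
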