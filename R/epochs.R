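#' EEG epoch container
#'
#' Holds a trials x channels x samples voltage tensor (microvolts) together
#' with its sampling rate, epoch start time and per-trial metadata. The time
#' axis of sample `s` is `t_start + (s - 1) / sfreq` seconds relative to
#' stimulus onset.
#'
#' @param data Numeric array `[trials, channels, samples]`.
#' @param info Tibble with one row per trial; expected columns include
#'   `subject`, `group`, `timepoint`, `stim_class` (and optionally `rt_ms`,
#'   `correct`).
#' @param sfreq Sampling frequency, Hz.
#' @param t_start Epoch start, seconds relative to stimulus onset.
#' @param montage The `montage` the channel axis refers to.
#' @param log Character vector of processing steps applied so far.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, info, sfreq, t_start, montage, log = character()) {
  if (length(dim(data)) != 3L) {
    stop_invalid("epoch data must be a trials x channels x samples array")
  }
  if (nrow(info) != dim(data)[1]) {
    stop_invalid("metadata rows (%d) must match trials (%d)", nrow(info), dim(data)[1])
  }
  if (!is.null(montage) && nrow(montage$channels) != dim(data)[2]) {
    stop_invalid("montage has %d channels, data %d", nrow(montage$channels), dim(data)[2])
  }
  if (sfreq <= 0) stop_invalid("sfreq must be positive")
  structure(
    list(
      data = data, info = tibble::as_tibble(info),
      sfreq = sfreq, t_start = t_start, montage = montage, log = log
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] ms\n",
    d[1], d[2], d[3], x$sfreq, x$t_start * 1000,
    (x$t_start + (d[3] - 1) / x$sfreq) * 1000
  ))
  if (length(x$log)) cat("  log:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

epoch_times <- function(x) sample_times(dim(x$data)[3], x$sfreq, x$t_start)

#' Stack of subject-level ERPs
#'
#' A `subjects x channels x samples` array of trial-averaged ERPs with one
#' metadata row per observation (`subject`, `group`, `timepoint`,
#' `stim_class`, `n_trials`). This is the unit the group-level statistics
#' operate on.
#'
#' @param data Numeric array `[observations, channels, samples]`.
#' @param info Tibble, one row per observation.
#' @inheritParams eeg_epochs
#' @return An object of class `erp_stack`.
#' @export
erp_stack <- function(data, info, sfreq, t_start, montage) {
  if (length(dim(data)) != 3L) {
    stop_invalid("ERP stack data must be an observations x channels x samples array")
  }
  if (nrow(info) != dim(data)[1]) {
    stop_invalid("metadata rows must match observations")
  }
  structure(
    list(
      data = data, info = tibble::as_tibble(info),
      sfreq = sfreq, t_start = t_start, montage = montage
    ),
    class = "erp_stack"
  )
}

#' @export
print.erp_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<erp_stack> %d ERPs x %d channels x %d samples @ %g Hz, t = [%g, %g] ms\n",
    d[1], d[2], d[3], x$sfreq, x$t_start * 1000,
    (x$t_start + (d[3] - 1) / x$sfreq) * 1000
  ))
  invisible(x)
}

#' @export
dim.erp_stack <- function(x) dim(x$data)

stack_times <- function(x) sample_times(dim(x$data)[3], x$sfreq, x$t_start)

# subset an erp_stack by observation index
stack_subset <- function(x, idx) {
  erp_stack(
    x$data[idx, , , drop = FALSE], x$info[idx, , drop = FALSE],
    x$sfreq, x$t_start, x$montage
  )
}

# average observations within metadata cells (e.g. collapse timepoints)
stack_average <- function(x, by) {
  by <- intersect(by, names(x$info))
  key <- do.call(paste, c(x$info[by], sep = "\r"))
  cells <- unique(key)
  d <- dim(x$data)
  out <- array(0, c(length(cells), d[2], d[3]))
  info <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    rows <- which(key == cells[i])
    out[i, , ] <- colMeans(array(
      x$data[rows, , , drop = FALSE],
      c(length(rows), d[2] * d[3])
    ))
    info[[i]] <- x$info[rows[1], by, drop = FALSE]
  }
  erp_stack(out, dplyr::bind_rows(info), x$sfreq, x$t_start, x$montage)
}

# restrict an erp_stack to a closed sample-index window
stack_crop_idx <- function(x, idx) {
  out <- x
  out$data <- x$data[, , idx, drop = FALSE]
  out$t_start <- x$t_start + (idx[1] - 1L) / x$sfreq
  out
}

#' Convert an ERP stack to a long tibble
#'
#' One row per observation x channel x sample, for plotting and tidy
#' summaries.
#'
#' @param x An `erp_stack`.
#' @param ... Unused.
#' @return A tibble with metadata columns plus `channel`, `time_ms`, `uv`.
#' @method as_tibble erp_stack
#' @export
as_tibble.erp_stack <- function(x, ...) {
  d <- dim(x$data)
  tms <- stack_times(x) * 1000
  ch <- x$montage$channels$channel
  grid <- tidyr::expand_grid(
    .obs = seq_len(d[1]), channel = ch, time_ms = tms
  )
  # aperm -> [samples, channels, obs]; as.vector then matches expand_grid order
  grid$uv <- as.vector(aperm(x$data, c(3L, 2L, 1L)))
  dplyr::bind_cols(x$info[grid$.obs, , drop = FALSE], grid[, -1L])
}

#' Write / read an epoch container directory
#'
#' The on-disk layout is a directory with `meta.csv` (one row per trial),
#' `attrs.json` (sampling rate, epoch start, channel labels, generator log)
#' and one voltage tensor per subject (`<subject>.rds`, named dimensions
#' trials / channels / samples). A montage file `montage.txt` is included.
#'
#' @param epochs An `eeg_epochs` object.
#' @param dir Directory to create.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` returns
#'   an `eeg_epochs`.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- dplyr::mutate(epochs$info, .row = dplyr::row_number())
  readr::write_csv(dplyr::select(info, -".row"), file.path(dir, "meta.csv"))
  jsonlite::write_json(
    list(
      sfreq = epochs$sfreq, t_start = epochs$t_start,
      channels = epochs$montage$channels$channel, log = epochs$log
    ),
    file.path(dir, "attrs.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_montage(epochs$montage, file.path(dir, "montage.txt"))
  for (sub in unique(info$subject)) {
    idx <- info$.row[info$subject == sub]
    x <- epochs$data[idx, , , drop = FALSE]
    dimnames(x) <- list(
      trial = NULL, channel = epochs$montage$channels$channel, sample = NULL
    )
    saveRDS(x, file.path(dir, paste0(sub, ".rds")))
  }
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  attrs <- jsonlite::read_json(file.path(dir, "attrs.json"), simplifyVector = TRUE)
  info <- readr::read_csv(file.path(dir, "meta.csv"), show_col_types = FALSE)
  montage <- read_montage(file.path(dir, "montage.txt"))
  subs <- unique(info$subject)
  mats <- lapply(subs, function(s) readRDS(file.path(dir, paste0(s, ".rds"))))
  n_tr <- sum(vapply(mats, function(m) dim(m)[1], integer(1)))
  data <- array(0, c(n_tr, dim(mats[[1]])[2], dim(mats[[1]])[3]))
  at <- 0L
  ord <- integer(0)
  for (i in seq_along(subs)) {
    k <- dim(mats[[i]])[1]
    data[at + seq_len(k), , ] <- mats[[i]]
    ord <- c(ord, which(info$subject == subs[i]))
    at <- at + k
  }
  eeg_epochs(
    data, info[ord, , drop = FALSE], attrs$sfreq, attrs$t_start,
    montage,
    log = attrs$log %||% character()
  )
}
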