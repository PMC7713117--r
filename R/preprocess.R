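#' Preprocessing configuration
#'
#' Defaults follow common ERP practice: 1-40 Hz zero-phase Butterworth
#' band-pass (4th order, applied forward-backward), average reference,
#' +/-100 microvolt maximum-absolute artifact threshold, baseline window
#' (-200, 0) ms, analysis crop (-200, 600) ms. All windows are closed
#' intervals in ms, mapped to nearest samples.
#'
#' @param band_low,band_high Band edges, Hz.
#' @param filter_order Butterworth order of the one-pass prototype.
#' @param baseline_window Baseline window (lo, hi) ms.
#' @param reject_threshold Max-absolute artifact rejection threshold,
#'   microvolts.
#' @param crop_window Analysis window (lo, hi) ms.
#' @return List of class `preproc_config`.
#' @export
preproc_config <- function(band_low = 1, band_high = 40, filter_order = 4,
                           baseline_window = c(-200, 0),
                           reject_threshold = 100,
                           crop_window = c(-200, 600)) {
  if (band_low <= 0 || band_high <= band_low) {
    stop_invalid("need 0 < band_low < band_high")
  }
  if (reject_threshold <= 0) stop_invalid("reject_threshold must be positive")
  structure(
    list(
      band_low = band_low, band_high = band_high, filter_order = filter_order,
      baseline_window = baseline_window, reject_threshold = reject_threshold,
      crop_window = crop_window
    ),
    class = "preproc_config"
  )
}

# forward-backward Butterworth on one trial (channels x samples), with
# reflection padding against edge transients
filtfilt_matrix <- function(mat, filt, n_pad) {
  n <- ncol(mat)
  pad_l <- mat[, pmin(n, seq(n_pad + 1L, 2L, by = -1L)), drop = FALSE]
  pad_r <- mat[, pmax(1L, seq(n - 1L, n - n_pad, by = -1L)), drop = FALSE]
  ext <- cbind(2 * mat[, 1] - pad_l, mat, 2 * mat[, n] - pad_r)
  out <- t(apply(ext, 1L, function(x) signal::filtfilt(filt, x)))
  out[, n_pad + seq_len(n), drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth IIR band-pass forward and backward
#' (`signal::filtfilt`), giving zero net phase shift: passband sinusoids keep
#' their amplitude and latency, stopband components are attenuated with the
#' squared one-pass magnitude response. Epochs are reflection-padded before
#' filtering so the edges see no step transient.
#'
#' @param epochs An `eeg_epochs`.
#' @param cfg A [preproc_config()].
#' @return Filtered `eeg_epochs`.
#' @export
bandpass_filter <- function(epochs, cfg = preproc_config()) {
  nyq <- epochs$sfreq / 2
  if (cfg$band_high >= nyq) {
    stop_invalid(
      "band_high %g Hz violates the Nyquist limit %g Hz",
      cfg$band_high, nyq
    )
  }
  filt <- signal::butter(cfg$filter_order,
    c(cfg$band_low, cfg$band_high) / nyq,
    type = "pass"
  )
  n_sp <- dim(epochs$data)[3]
  # one low-frequency period of padding, capped at epoch length - 1
  n_pad <- min(n_sp - 1L, as.integer(round(epochs$sfreq / cfg$band_low)))
  for (tr in seq_len(dim(epochs$data)[1])) {
    epochs$data[tr, , ] <- filtfilt_matrix(
      epochs$data[tr, , , drop = FALSE][1, , ], filt, n_pad
    )
  }
  epochs$log <- c(
    epochs$log,
    sprintf(
      "bandpass %g-%g Hz (Butterworth order %d, zero-phase)",
      cfg$band_low, cfg$band_high, cfg$filter_order
    )
  )
  epochs
}

#' Re-reference to the channel average
#'
#' Subtracts, at every trial and sample, the instantaneous mean over
#' channels, so the channel mean is zero everywhere. Idempotent.
#'
#' @param epochs An `eeg_epochs` with at least 2 channels.
#' @return Re-referenced `eeg_epochs`.
#' @export
rereference_average <- function(epochs) {
  d <- dim(epochs$data)
  if (d[2] < 2L) stop_invalid("average reference needs >= 2 channels")
  for (tr in seq_len(d[1])) {
    mat <- epochs$data[tr, , , drop = FALSE][1, , ]
    epochs$data[tr, , ] <- sweep(mat, 2L, colMeans(mat))
  }
  epochs$log <- c(epochs$log, "average reference")
  epochs
}

#' Baseline-correct each trial and channel
#'
#' Subtracts the per-trial, per-channel mean over the baseline window
#' (default: the 200 ms pre-stimulus period).
#'
#' @param epochs An `eeg_epochs`.
#' @param window Baseline window (lo, hi) ms; must lie inside the epoch.
#' @return Baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  d <- dim(epochs$data)
  idx <- window_to_idx(window, epochs$sfreq, epochs$t_start, d[3])
  for (tr in seq_len(d[1])) {
    mat <- epochs$data[tr, , , drop = FALSE][1, , ]
    epochs$data[tr, , ] <- mat - rowMeans(mat[, idx, drop = FALSE])
  }
  epochs$log <- c(
    epochs$log,
    sprintf("baseline [%g, %g] ms", window[1], window[2])
  )
  epochs
}

#' Reject trials exceeding a max-absolute voltage threshold
#'
#' A deterministic stand-in for visual artifact screening: any trial whose
#' maximum absolute voltage on any channel exceeds `threshold` microvolts is
#' removed. The report counts rejections per subject x group x timepoint x
#' stimulus-class cell; cells losing every trial are flagged (`all_rejected`)
#' and downstream averaging refuses them.
#'
#' @param epochs An `eeg_epochs`.
#' @param threshold Positive threshold, microvolts.
#' @return List with `epochs` (surviving trials) and `report` (tibble:
#'   cell columns, `n_total`, `n_rejected`, `fraction`, `all_rejected`).
#' @export
reject_artifact_trials <- function(epochs, threshold = 100) {
  if (threshold <= 0) stop_invalid("threshold must be positive")
  d <- dim(epochs$data)
  peak <- vapply(
    seq_len(d[1]),
    function(tr) max(abs(epochs$data[tr, , ])), numeric(1)
  )
  keep <- peak <= threshold
  cell_cols <- intersect(
    c("subject", "group", "timepoint", "stim_class"),
    names(epochs$info)
  )
  report <- epochs$info |>
    dplyr::mutate(.rejected = !keep) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell_cols))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_rejected = sum(.data$.rejected),
      fraction = sum(.data$.rejected) / dplyr::n(),
      all_rejected = all(.data$.rejected),
      .groups = "drop"
    )
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$info <- epochs$info[keep, , drop = FALSE]
  out$log <- c(
    out$log,
    sprintf(
      "artifact rejection at +/-%g uV: %d/%d trials removed",
      threshold, sum(!keep), length(keep)
    )
  )
  list(epochs = out, report = report)
}

#' Crop to an analysis window and average trials into subject ERPs
#'
#' Restricts the epoch to a closed window (sample count =
#' `round(span * sfreq) + 1`) and averages trials within each metadata cell
#' (default: subject x group x timepoint x stimulus class), returning an
#' [erp_stack()] whose `n_trials` records how many trials each ERP averages.
#'
#' @param epochs An `eeg_epochs` with at least one trial.
#' @param window Analysis window (lo, hi) ms.
#' @param by Metadata columns defining the averaging cells.
#' @return An `erp_stack`.
#' @export
crop_and_average <- function(epochs, window = c(-200, 600),
                             by = c("subject", "group", "timepoint", "stim_class")) {
  d <- dim(epochs$data)
  if (d[1] < 1L) stop_invalid("no trials to average")
  idx <- window_to_idx(window, epochs$sfreq, epochs$t_start, d[3])
  by <- intersect(by, names(epochs$info))
  key <- do.call(paste, c(epochs$info[by], sep = "\r"))
  cells <- unique(key)
  n_ch <- d[2]
  n_sp <- length(idx)
  out <- array(0, c(length(cells), n_ch, n_sp))
  info <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    rows <- which(key == cells[i])
    sub <- epochs$data[rows, , idx, drop = FALSE]
    out[i, , ] <- colMeans(array(sub, c(length(rows), n_ch * n_sp)))
    meta <- epochs$info[rows[1], by, drop = FALSE]
    meta$n_trials <- length(rows)
    if ("rt_ms" %in% names(epochs$info)) {
      ok <- epochs$info$correct[rows] %||% rep(TRUE, length(rows))
      meta$rt_ms <- mean(epochs$info$rt_ms[rows][ok], na.rm = TRUE)
    }
    info[[i]] <- meta
  }
  erp_stack(
    out, dplyr::bind_rows(info), epochs$sfreq,
    epochs$t_start + (idx[1] - 1L) / epochs$sfreq, epochs$montage
  )
}

#' Run the standard preprocessing chain
#'
#' Filter -> average reference -> artifact rejection -> baseline correction
#' -> crop and average, in that order; the order is recorded in the epochs
#' log and echoed in the returned report. For target-locked epochs, only
#' correct-response trials enter the average when a `correct` metadata column
#' is present (`correct_only = TRUE`).
#'
#' @param epochs An `eeg_epochs`.
#' @param cfg A [preproc_config()].
#' @param correct_only Drop incorrect-response trials before averaging
#'   (applies only when the metadata has a `correct` column).
#' @return List with `erps` (an `erp_stack`), `rejection` (report tibble) and
#'   `order` (character vector of applied stages).
#' @export
preprocess_epochs <- function(epochs, cfg = preproc_config(),
                              correct_only = TRUE) {
  epochs <- bandpass_filter(epochs, cfg)
  epochs <- rereference_average(epochs)
  rej <- reject_artifact_trials(epochs, cfg$reject_threshold)
  epochs <- rej$epochs
  if (any(rej$report$all_rejected)) {
    bad <- rej$report[rej$report$all_rejected, , drop = FALSE]
    stop_invalid(
      "artifact rejection removed every trial in %d cell(s); cannot average",
      nrow(bad)
    )
  }
  epochs <- baseline_correct(epochs, cfg$baseline_window)
  if (correct_only && "correct" %in% names(epochs$info) &&
    any(!epochs$info$correct)) {
    keep <- epochs$info$correct
    epochs$data <- epochs$data[keep, , , drop = FALSE]
    epochs$info <- epochs$info[keep, , drop = FALSE]
    epochs$log <- c(epochs$log, "correct-response trials only")
  }
  erps <- crop_and_average(epochs, cfg$crop_window)
  list(
    erps = erps, rejection = rej$report,
    order = c("filter", "average-reference", "reject", "baseline", "average")
  )
}
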