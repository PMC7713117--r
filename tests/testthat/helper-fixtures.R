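# shared fixture builders; everything is generated in code, no stored data

# erp_stack from an explicit obs x channels x samples array
stack_from_array <- function(data, group = NULL, timepoint = NULL,
                             subject = NULL, sfreq = 256, t_start = 0) {
  n <- dim(data)[1]
  info <- tibble::tibble(
    subject = subject %||% sprintf("s%03d", seq_len(n)),
    group = group %||% rep("A", n),
    timepoint = timepoint %||% rep("T1", n),
    stim_class = "cue"
  )
  erp_stack(data, info, sfreq, t_start, make_montage(dim(data)[2], "ring"))
}

# paired stack: same subjects at two timepoints, given per-subject matrices
paired_stack <- function(mats_t1, mats_t3, sfreq = 256, t_start = 0) {
  n <- length(mats_t1)
  d <- dim(mats_t1[[1]])
  data <- array(0, c(2 * n, d[1], d[2]))
  for (i in seq_len(n)) {
    data[i, , ] <- mats_t1[[i]]
    data[n + i, , ] <- mats_t3[[i]]
  }
  info <- tibble::tibble(
    subject = rep(sprintf("s%03d", seq_len(n)), 2),
    group = "A",
    timepoint = rep(c("T1", "T3"), each = n),
    stim_class = "cue"
  )
  erp_stack(data, info, sfreq, t_start, make_montage(d[1], "ring"))
}

# epochs with a single constant trial pattern replicated
epochs_from_trials <- function(trials, sfreq = 256, t_start = -0.2,
                               info = NULL) {
  n <- length(trials)
  d <- dim(trials[[1]])
  data <- array(0, c(n, d[1], d[2]))
  for (i in seq_len(n)) data[i, , ] <- trials[[i]]
  info <- info %||% tibble::tibble(
    subject = "s001", group = "A", timepoint = "T1", stim_class = "cue",
    trial = seq_len(n)
  )
  eeg_epochs(data, info, sfreq, t_start, make_montage(d[1], "ring"))
}

# single-component plan with controllable randomness
one_component_plan <- function(window = c(33, 107), base = 2, polarity = 1,
                               subject_sd = 0, trial_sd = 0,
                               centroid = "vertex", deltas = NULL,
                               couplings = NULL) {
  effect_plan(
    list(erp_component("C1", "cue", window,
      base_amp = base,
      polarity = polarity, subject_sd = subject_sd, trial_sd = trial_sd,
      centroid = centroid
    )),
    deltas = deltas, couplings = couplings
  )
}

expect_invalid <- function(expr) {
  expect_error(expr, class = "erpcluster_invalid_argument")
}
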