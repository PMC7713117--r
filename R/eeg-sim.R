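#' Noise specification for synthetic EEG
#'
#' The generator's background activity is spatially correlated Gaussian noise
#' with 1/f spectral shaping: each channel's spectrum is scaled by
#' `f^(-exponent/2)` (power ~ 1/f^exponent) and channels are mixed through a
#' squared-exponential spatial covariance over sensor distance, mimicking the
#' smooth spatial structure of scalp EEG. Real EEG additionally carries
#' ocular/cardiac artifacts, line noise and non-stationarity, none of which
#' are simulated.
#'
#' @param sd Per-channel noise standard deviation, microvolts.
#' @param spatial_scale Correlation length as a fraction of the montage
#'   radius.
#' @param exponent Spectral exponent (power ~ 1/f^exponent); 0 = white.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sd = 3, spatial_scale = 0.5, exponent = 1) {
  if (sd < 0 || spatial_scale < 0) {
    stop_invalid("noise amplitudes must be non-negative")
  }
  structure(list(sd = sd, spatial_scale = spatial_scale, exponent = exponent),
    class = "noise_spec"
  )
}

# channel-mixing factor L (C = L L') for the spatial covariance
noise_mixer <- function(montage, spatial_scale) {
  pos <- montage_positions(montage)
  r <- max(sqrt(rowSums(pos^2)), 1e-12)
  if (spatial_scale == 0) {
    return(diag(nrow(pos)))
  }
  lambda <- spatial_scale * r
  d2 <- as.matrix(stats::dist(pos))^2
  C <- exp(-d2 / (2 * lambda^2))
  t(chol(C + diag(1e-8, nrow(C))))
}

# 1/f frequency-domain gains, normalised to unit output variance
noise_gains <- function(n_samples, sfreq, exponent) {
  f <- seq(0, sfreq, length.out = n_samples + 1L)[seq_len(n_samples)]
  f <- pmin(f, sfreq - f) # two-sided spectrum
  f[f < 1] <- 1 # flatten below 1 Hz to keep finite power
  g <- f^(-exponent / 2)
  g / sqrt(mean(g^2))
}

# one trial of noise: channels x samples matrix, unit per-channel sd before
# scaling by spec$sd
noise_trial <- function(n_channels, n_samples, gains, mixer, sd) {
  noise_trials(1L, n_channels, n_samples, gains, mixer, sd)[1, , ]
}

# batch of noise trials as an array [n_trials, channels, samples]; all
# trials share one FFT call, which dominates the generator's runtime
noise_trials <- function(n_trials, n_channels, n_samples, gains, mixer, sd) {
  out <- array(0, c(n_trials, n_channels, n_samples))
  if (sd == 0) {
    return(out)
  }
  white <- matrix(
    rnorm(n_channels * n_samples * n_trials),
    n_samples, n_channels * n_trials
  )
  shaped <- Re(stats::mvfft(stats::mvfft(white) * gains, inverse = TRUE)) /
    n_samples
  # mvfft round trip preserves the unit variance enforced by the gains
  for (tr in seq_len(n_trials)) {
    cols <- (tr - 1L) * n_channels + seq_len(n_channels)
    out[tr, , ] <- sd * (mixer %*% t(shaped[, cols, drop = FALSE]))
  }
  out
}

# temporal profile of a component over the epoch's time axis (0..1)
component_profile <- function(comp, times_s) {
  t_ms <- times_s * 1000
  w <- comp$window_ms
  if (comp$profile == "gaussian") {
    mu <- mean(w)
    sig <- comp$width_ms
    return(exp(-(t_ms - mu)^2 / (2 * sig^2)))
  }
  # plateau with raised-cosine shoulders of width_ms
  p <- numeric(length(t_ms))
  p[t_ms >= w[1] & t_ms <= w[2]] <- 1
  lo <- t_ms < w[1] & t_ms >= w[1] - comp$width_ms
  hi <- t_ms > w[2] & t_ms <= w[2] + comp$width_ms
  p[lo] <- 0.5 * (1 + cos(pi * (w[1] - t_ms[lo]) / comp$width_ms))
  p[hi] <- 0.5 * (1 + cos(pi * (t_ms[hi] - w[2]) / comp$width_ms))
  p
}

# topography weights: exactly 1 inside the core radius, Gaussian falloff
# outside; |w| <= 1 always
component_topography <- function(comp, montage) {
  pos <- montage_positions(montage)
  r <- max(sqrt(rowSums(pos^2)), 1e-12)
  ctr <- if (is.character(comp$centroid)) {
    region_coords(comp$centroid, montage)
  } else {
    as.numeric(comp$centroid)
  }
  d <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
  sig <- comp$falloff * r
  core <- comp$core_frac * sig
  w <- ifelse(d <= core, 1, exp(-(d - core)^2 / (2 * sig^2)))
  # sparse montages can leave the core empty; the nearest channel then
  # carries the full planted amplitude so the mask is never empty
  if (!any(d <= core)) w[which.min(d)] <- 1
  w
}

#' Planted mask of a component: core channels and latency-window samples
#'
#' Returns the exact (channel, sample) mask over which the generator plants a
#' component's amplitude: the channels whose topography weight is 1 and the
#' samples inside the latency window. The mean ERP difference over this mask
#' converges to the planted delta.
#'
#' @param comp An [erp_component()].
#' @param montage The montage in use.
#' @param sfreq,t_start,n_samples Epoch timing.
#' @return List with integer vectors `channels` and `samples`, plus
#'   `window_ms`.
#' @export
component_mask <- function(comp, montage, sfreq, t_start, n_samples) {
  w <- component_topography(comp, montage)
  idx <- window_to_idx(comp$window_ms, sfreq, t_start, n_samples)
  list(
    channels = which(w >= 1 - 1e-12), samples = idx,
    window_ms = comp$window_ms
  )
}

check_plan_windows <- function(plan, sfreq, t_start, n_samples) {
  t_ms <- sample_times(n_samples, sfreq, t_start) * 1000
  for (comp in plan$components) {
    if (comp$window_ms[1] < t_ms[1] || comp$window_ms[2] > t_ms[length(t_ms)]) {
      stop_invalid(
        "component %s window [%g, %g] ms lies outside the epoch",
        comp$name, comp$window_ms[1], comp$window_ms[2]
      )
    }
  }
}

# session-split of amplitude variance: stable subject part cancels in paired
# contrasts, session part does not
AMP_SESSION_FRAC <- 0.5

# per-subject simulation shared by generate_eeg_epochs and simulate_erp_study.
# Returns list(data = trials x channels x samples, rt_ms, correct)
sim_subject_trials <- function(group, timepoint, stim_class, n_trials,
                               comps, plan, montage, times_s,
                               gains, mixer, noise, stable_amp_offsets,
                               rt_params) {
  n_ch <- nrow(montage$channels)
  n_sp <- length(times_s)
  profs <- lapply(comps, component_profile, times_s = times_s)
  topos <- lapply(comps, component_topography, montage = montage)
  data <- array(0, c(n_trials, n_ch, n_sp))

  # session-level amplitude offsets
  sess <- vapply(comps, function(comp) {
    rnorm(1, 0, comp$subject_sd * sqrt(AMP_SESSION_FRAC))
  }, numeric(1))

  z_rt <- rnorm(n_trials)
  rt_ms <- stats::qlnorm(stats::pnorm(z_rt), rt_params$mu, rt_params$sigma)
  correct <- rbinom(n_trials, 1L, 1 - rt_params$error_prob) == 1L

  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    delta <- plan_delta(plan, group, timepoint, comp$name)
    amp0 <- comp$polarity * comp$base_amp + delta +
      stable_amp_offsets[[comp$name]] + sess[ci]
    r <- plan$couplings$r[match(comp$name, plan$couplings$component)]
    r <- if (is.na(r) || length(r) == 0) 0 else r
    jit <- comp$trial_sd *
      (r * z_rt + sqrt(max(0, 1 - r^2)) * rnorm(n_trials))
    amps <- amp0 + jit
    bump <- outer(topos[[ci]], profs[[ci]]) # channels x samples
    data <- data + array(
      tcrossprod(amps, as.vector(bump)),
      c(n_trials, n_ch, n_sp)
    )
  }
  if (noise$sd > 0) {
    data <- data + noise_trials(n_trials, n_ch, n_sp, gains, mixer, noise$sd)
  }
  list(data = data, rt_ms = rt_ms, correct = correct)
}

rt_cell_params <- function(plan, group, timepoint, subject_rt_factor,
                           subject_cv) {
  if (is.null(plan$behaviour)) {
    return(list(mu = log(430), sigma = 0.14, error_prob = 0))
  }
  cell <- plan_behaviour_cell(plan, group, timepoint)
  m <- cell$rt_mean_ms * subject_rt_factor
  cv <- max(0.02, subject_cv + (cell$rt_cv - 0.14))
  sig2 <- log(1 + cv^2)
  list(
    mu = log(m) - sig2 / 2, sigma = sqrt(sig2),
    error_prob = cell$error_prob, cv = cv
  )
}

#' Generate synthetic EEG epoch sets for a longitudinal two-arm study
#'
#' Simulates stimulus-locked EEG epochs for every subject x timepoint cell of
#' the design. Each trial is the sum of the plan's component templates
#' (temporal profile x topography x signed amplitude, with the amplitude
#' offset by the planted (group, timepoint) delta, a subject/session random
#' effect, and trial-to-trial jitter optionally coupled to that trial's
#' reaction time) plus spatially correlated 1/f-shaped Gaussian noise.
#' Bit-reproducible under a fixed seed.
#'
#' @param design List with `groups` (named integer vector of group sizes,
#'   e.g. `c(MT = 50, CT = 31)`) and `timepoints` (character).
#' @param montage A `montage`.
#' @param plan An [effect_plan()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param n_trials Trials per subject x timepoint x stimulus class.
#' @param sfreq Sampling rate, Hz.
#' @param t_start,t_end Epoch limits, seconds relative to stimulus onset.
#' @param stim_classes Which epoch families to generate.
#' @return Named list of `eeg_epochs`, one per stimulus class. Target-epoch
#'   metadata carries `rt_ms` and `correct` per trial.
#' @export
generate_eeg_epochs <- function(design, montage, plan, noise = noise_spec(),
                                seed = 1, n_trials = 60, sfreq = 256,
                                t_start = -0.5, t_end = 0.8,
                                stim_classes = c("cue", "target")) {
  validate_montage(montage)
  n_sp <- as.integer(round((t_end - t_start) * sfreq)) + 1L
  check_plan_windows(plan, sfreq, t_start, n_sp)
  times_s <- sample_times(n_sp, sfreq, t_start)
  gains <- noise_gains(n_sp, sfreq, noise$exponent)
  mixer <- noise_mixer(montage, noise$spatial_scale)
  n_ch <- nrow(montage$channels)

  groups <- design$groups
  tps <- design$timepoints
  subjects <- unlist(lapply(names(groups), function(g) {
    sprintf("%s%03d", g, seq_len(groups[[g]]))
  }))
  sub_group <- rep(names(groups), groups)

  out <- list()
  for (cls in stim_classes) {
    comps <- Filter(function(c) c$stim_class == cls, plan$components)
    n_obs <- length(subjects) * length(tps)
    data <- array(0, c(n_obs * n_trials, n_ch, n_sp))
    info <- vector("list", n_obs)
    with_seed(derive_seed(seed, match(cls, c("cue", "target"), nomatch = 3L)), {
      row <- 0L
      cell <- 0L
      for (si in seq_along(subjects)) {
        stable <- lapply(plan$components, function(comp) {
          rnorm(1, 0, comp$subject_sd * sqrt(1 - AMP_SESSION_FRAC))
        })
        names(stable) <- names(plan$components)
        rt_factor <- exp(rnorm(1, 0, plan$subject_rt_sd_log) -
          plan$subject_rt_sd_log^2 / 2)
        cv_s <- max(0.02, rnorm(1, 0.14, plan$subject_cv_sd))
        for (tp in tps) {
          cell <- cell + 1L
          rtp <- rt_cell_params(plan, sub_group[si], tp, rt_factor, cv_s)
          sim <- sim_subject_trials(
            sub_group[si], tp, cls, n_trials, comps, plan, montage,
            times_s, gains, mixer, noise, stable, rtp
          )
          data[row + seq_len(n_trials), , ] <- sim$data
          info[[cell]] <- tibble::tibble(
            subject = subjects[si], group = sub_group[si], timepoint = tp,
            stim_class = cls, trial = seq_len(n_trials),
            rt_ms = sim$rt_ms, correct = sim$correct
          )
          row <- row + n_trials
        }
      }
    })
    out[[cls]] <- eeg_epochs(
      data, dplyr::bind_rows(info), sfreq, t_start, montage,
      log = sprintf("simulated (seed %d, class %s)", seed, cls)
    )
  }
  out
}

#' Simulate a study directly at the subject-ERP level
#'
#' Runs the same generative model as [generate_eeg_epochs()] but averages
#' each subject x timepoint cell to its ERP on the fly, returning an
#' [erp_stack()] per stimulus class. This keeps large designs (50+ subjects,
#' three timepoints) tractable for power and error-rate simulations.
#'
#' @inheritParams generate_eeg_epochs
#' @return Named list of `erp_stack` objects.
#' @export
simulate_erp_study <- function(design, montage, plan, noise = noise_spec(),
                               seed = 1, n_trials = 20, sfreq = 256,
                               t_start = -0.5, t_end = 0.8,
                               stim_classes = c("cue", "target")) {
  validate_montage(montage)
  n_sp <- as.integer(round((t_end - t_start) * sfreq)) + 1L
  check_plan_windows(plan, sfreq, t_start, n_sp)
  times_s <- sample_times(n_sp, sfreq, t_start)
  gains <- noise_gains(n_sp, sfreq, noise$exponent)
  mixer <- noise_mixer(montage, noise$spatial_scale)
  n_ch <- nrow(montage$channels)

  groups <- design$groups
  tps <- design$timepoints
  subjects <- unlist(lapply(names(groups), function(g) {
    sprintf("%s%03d", g, seq_len(groups[[g]]))
  }))
  sub_group <- rep(names(groups), groups)

  out <- list()
  for (cls in stim_classes) {
    comps <- Filter(function(c) c$stim_class == cls, plan$components)
    n_obs <- length(subjects) * length(tps)
    data <- array(0, c(n_obs, n_ch, n_sp))
    info <- vector("list", n_obs)
    with_seed(derive_seed(seed, match(cls, c("cue", "target"), nomatch = 3L)), {
      cell <- 0L
      for (si in seq_along(subjects)) {
        stable <- lapply(plan$components, function(comp) {
          rnorm(1, 0, comp$subject_sd * sqrt(1 - AMP_SESSION_FRAC))
        })
        names(stable) <- names(plan$components)
        rt_factor <- exp(rnorm(1, 0, plan$subject_rt_sd_log) -
          plan$subject_rt_sd_log^2 / 2)
        cv_s <- max(0.02, rnorm(1, 0.14, plan$subject_cv_sd))
        for (tp in tps) {
          cell <- cell + 1L
          rtp <- rt_cell_params(plan, sub_group[si], tp, rt_factor, cv_s)
          sim <- sim_subject_trials(
            sub_group[si], tp, cls, n_trials, comps, plan, montage,
            times_s, gains, mixer, noise, stable, rtp
          )
          data[cell, , ] <- colMeans(array(
            sim$data, c(n_trials, n_ch * n_sp)
          ))
          info[[cell]] <- tibble::tibble(
            subject = subjects[si], group = sub_group[si], timepoint = tp,
            stim_class = cls, n_trials = n_trials,
            rt_ms = mean(sim$rt_ms[sim$correct]),
            error_rate = mean(!sim$correct)
          )
        }
      }
    })
    out[[cls]] <- erp_stack(
      data, dplyr::bind_rows(info), sfreq, t_start, montage
    )
  }
  out
}

#' Generate a null ERP stack (no condition effects)
#'
#' Subject-level ERPs containing only spatially correlated 1/f Gaussian
#' noise, split into two groups. Group labels are exchangeable by
#' construction, so any test run on this stack operates under its null
#' hypothesis; used for family-wise error-rate simulations.
#'
#' @param n_per_group Integer vector of two group sizes.
#' @param n_channels,n_samples Dimensions of each ERP.
#' @param sfreq Sampling rate, Hz (time axis starts at 0).
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return An `erp_stack` with groups `"A"` and `"B"`.
#' @export
make_null_erp_stack <- function(n_per_group = c(15, 15), n_channels = 16,
                                n_samples = 150, sfreq = 256,
                                noise = noise_spec(), seed = 1) {
  montage <- make_montage(n_channels, "reduced-head")
  gains <- noise_gains(n_samples, sfreq, noise$exponent)
  mixer <- noise_mixer(montage, noise$spatial_scale)
  n <- sum(n_per_group)
  data <- array(0, c(n, n_channels, n_samples))
  with_seed(seed, {
    for (i in seq_len(n)) {
      data[i, , ] <- noise_trial(n_channels, n_samples, gains, mixer, noise$sd)
    }
  })
  info <- tibble::tibble(
    subject = sprintf("S%03d", seq_len(n)),
    group = rep(c("A", "B"), n_per_group),
    timepoint = "T1", stim_class = "cue", n_trials = 1L
  )
  erp_stack(data, info, sfreq, 0, montage)
}
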