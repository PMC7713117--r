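#' Define an ERP component template
#'
#' A component is a transient voltage deflection with a latency window, a
#' scalp topography and an amplitude. The temporal profile is, by default, a
#' plateau spanning the latency window with raised-cosine shoulders of
#' `width_ms` on either side ("plateau"); a Gaussian bump centred on the
#' window midpoint is available as `profile = "gaussian"`. The topography has
#' weight exactly 1 within `core_frac` of the falloff scale around the
#' centroid and Gaussian falloff outside, so the planted amplitude is
#' recovered exactly as the mean over the core channels and the latency
#' window.
#'
#' @param name Component label (e.g. "P1", "N1").
#' @param stim_class `"cue"` or `"target"` epoch family the component loads on.
#' @param window_ms Latency window (lo, hi) in ms post-stimulus.
#' @param width_ms Shoulder width (plateau) or Gaussian sigma, ms.
#' @param centroid Named scalp region (see `region_coords`) or numeric (x, y).
#' @param base_amp Unsigned base amplitude, microvolts.
#' @param polarity +1 or -1.
#' @param subject_sd Between-subject SD of the signed amplitude, microvolts.
#' @param trial_sd Trial-to-trial SD of the signed amplitude, microvolts.
#' @param falloff Topography Gaussian falloff scale as a fraction of the
#'   montage radius.
#' @param core_frac Fraction of the falloff scale within which the weight is
#'   exactly 1 (the "planted channels").
#' @param profile `"plateau"` or `"gaussian"`.
#' @return A list of class `erp_component`.
#' @export
erp_component <- function(name, stim_class, window_ms, width_ms = 15,
                          centroid = "vertex", base_amp = 2, polarity = 1,
                          subject_sd = 2, trial_sd = 4,
                          falloff = 0.4, core_frac = 0.5,
                          profile = c("plateau", "gaussian")) {
  if (length(window_ms) != 2L || window_ms[2] <= window_ms[1]) {
    stop_invalid("component window must be (lo, hi) ms with lo < hi")
  }
  if (!polarity %in% c(-1, 1)) stop_invalid("polarity must be +1 or -1")
  structure(
    list(
      name = name, stim_class = match.arg(stim_class, c("cue", "target")),
      window_ms = as.numeric(window_ms), width_ms = width_ms,
      centroid = centroid, base_amp = base_amp, polarity = polarity,
      subject_sd = subject_sd, trial_sd = trial_sd,
      falloff = falloff, core_frac = core_frac,
      profile = match.arg(profile)
    ),
    class = "erp_component"
  )
}

#' Assemble an effect plan
#'
#' An effect plan is the generator's full specification of what the synthetic
#' study contains: the ERP component templates, the planted
#' (group, timepoint, component) amplitude offsets, the behavioural model for
#' each (group, timepoint) cell, and the trial-level couplings between
#' component amplitudes and reaction time.
#'
#' @param components List of [erp_component()] objects.
#' @param deltas Tibble `group`, `timepoint`, `component`, `delta_uv`:
#'   signed microvolt offsets added to the signed component amplitude.
#'   Missing cells mean 0.
#' @param behaviour Tibble with one row per `group` x `timepoint`:
#'   `rt_mean_ms`, `rt_cv`, `error_prob` (per-trial), `breath_mean`,
#'   `breath_sd` (accuracy %, between-subject SD).
#' @param couplings Tibble `component`, `r`: trial-level Gaussian-copula
#'   correlation in [-1, 1] between the component's signed amplitude and RT.
#' @param subject_rt_sd_log Between-subject SD of log RT mean.
#' @param subject_cv_sd Between-subject SD of the RT coefficient of variation.
#' @param subject_error_sd_logit Between-subject SD of the per-trial error
#'   log-odds.
#' @return A list of class `effect_plan`.
#' @seealso [default_effect_plan()]
#' @export
effect_plan <- function(components, deltas = NULL, behaviour = NULL,
                        couplings = NULL,
                        subject_rt_sd_log = 0.11, subject_cv_sd = 0.03,
                        subject_error_sd_logit = 0.5) {
  stopifnot(is.list(components), length(components) >= 1L)
  nm <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_invalid("component names must be unique")
  names(components) <- nm
  if (is.null(deltas)) {
    deltas <- tibble::tibble(
      group = character(), timepoint = character(),
      component = character(), delta_uv = numeric()
    )
  }
  if (!is.null(couplings) && nrow(couplings) &&
    any(abs(couplings$r) > 1)) {
    stop_invalid("coupling coefficients must lie in [-1, 1]")
  }
  structure(
    list(
      components = components, deltas = tibble::as_tibble(deltas),
      behaviour = if (!is.null(behaviour)) tibble::as_tibble(behaviour),
      couplings = if (!is.null(couplings)) {
        tibble::as_tibble(couplings)
      } else {
        tibble::tibble(component = character(), r = numeric())
      },
      subject_rt_sd_log = subject_rt_sd_log,
      subject_cv_sd = subject_cv_sd,
      subject_error_sd_logit = subject_error_sd_logit
    ),
    class = "effect_plan"
  )
}

#' The default synthetic study: a two-arm longitudinal attention-training RCT
#'
#' Encodes the study conditions the package's simulations assume throughout:
#' a mindfulness-training arm (MT, n = 50) and a computer cognitive-training
#' arm (CT, n = 31) measured at baseline (T1), post-intervention (T2) and
#' 6-month follow-up (T3) on an AX-CPT with cue- and target-locked ERPs.
#'
#' ERP components and planted effects: a left parieto-occipital P1
#' (33-107 ms) and a parietal-temporal N1 (155-190 ms) to the cue, gaining
#' amplitude in the MT arm by T3 (standardised effects ~0.65 and ~0.55); an
#' occipital N1-P2 complex (178-235 ms) shifting negative in the CT arm by T3
#' (~0.75); a centroparietal P3 (230-400 ms) to the target, growing in the MT
#' arm by T3 (~0.36). Behavioural cells reproduce the baseline summaries
#' (RT 433/436 ms, RTCV 0.14, errors 0.45/0.39%, breath-counting accuracy
#' 44.8/53.4%) with errors and RTCV improving over time in both arms, and
#' breath-counting improving only under MT. Trial-level couplings tie the N1
#' amplitude to RT at +0.24 and the P3 amplitude to RT at -0.19.
#'
#' @return An [effect_plan()].
#' @export
default_effect_plan <- function() {
  comps <- list(
    erp_component("P1", "cue", c(33, 107),
      width_ms = 15,
      centroid = "left-parieto-occipital", base_amp = 3, polarity = 1,
      subject_sd = 2, trial_sd = 4
    ),
    erp_component("N1", "cue", c(155, 190),
      width_ms = 12,
      centroid = "parietal-temporal", base_amp = 2, polarity = -1,
      subject_sd = 2, trial_sd = 4
    ),
    erp_component("P2", "cue", c(178, 235),
      width_ms = 15,
      centroid = "occipital", base_amp = 1.5, polarity = 1,
      subject_sd = 2, trial_sd = 4
    ),
    erp_component("P3", "target", c(230, 400),
      width_ms = 25,
      centroid = "centroparietal", base_amp = 4, polarity = 1,
      subject_sd = 2, trial_sd = 4
    )
  )
  deltas <- tibble::tribble(
    ~group, ~timepoint, ~component, ~delta_uv,
    "MT", "T2", "N1", -0.6, # sub-threshold trend at post-intervention
    "MT", "T3", "P1", 1.3,
    "MT", "T3", "N1", -1.1,
    "MT", "T3", "P3", 0.72,
    "CT", "T3", "P2", -1.5 # N1-P2 negative shift under computer training
  )
  behaviour <- tibble::tribble(
    ~group, ~timepoint, ~rt_mean_ms, ~rt_cv, ~error_prob, ~breath_mean, ~breath_sd,
    "MT", "T1", 433.3, 0.140, 0.0045, 44.8, 32.7,
    "MT", "T2", 430.0, 0.125, 0.0030, 62.6, 32.7,
    "MT", "T3", 428.0, 0.120, 0.0026, 58.4, 32.7,
    "CT", "T1", 436.3, 0.140, 0.0039, 53.4, 34.8,
    "CT", "T2", 433.0, 0.128, 0.0035, 54.0, 34.8,
    "CT", "T3", 431.0, 0.123, 0.0033, 54.5, 34.8
  )
  couplings <- tibble::tibble(component = c("N1", "P3"), r = c(0.24, -0.19))
  effect_plan(comps, deltas, behaviour, couplings)
}

#' A null effect plan: same templates, no planted group-by-time effects
#'
#' Useful for false-positive-rate simulations: components and behavioural
#' baselines are retained but all deltas, time trends and couplings are
#' removed, so group and time labels are exchangeable.
#'
#' @return An [effect_plan()].
#' @export
null_effect_plan <- function() {
  plan <- default_effect_plan()
  base <- plan$behaviour |>
    dplyr::filter(.data$timepoint == "T1") |>
    dplyr::summarise(
      rt_mean_ms = mean(.data$rt_mean_ms), rt_cv = mean(.data$rt_cv),
      error_prob = mean(.data$error_prob),
      breath_mean = mean(.data$breath_mean), breath_sd = mean(.data$breath_sd)
    )
  behaviour <- tidyr::expand_grid(
    group = c("MT", "CT"), timepoint = c("T1", "T2", "T3")
  ) |>
    dplyr::bind_cols(base[rep(1, 6), ])
  effect_plan(plan$components,
    deltas = NULL, behaviour = behaviour,
    couplings = NULL
  )
}

# signed amplitude offset for (group, timepoint, component); 0 when unset
plan_delta <- function(plan, group, timepoint, component) {
  d <- plan$deltas
  hit <- d$group == group & d$timepoint == timepoint & d$component == component
  if (any(hit)) sum(d$delta_uv[hit]) else 0
}

plan_behaviour_cell <- function(plan, group, timepoint) {
  b <- plan$behaviour
  if (is.null(b)) stop_invalid("effect plan has no behavioural model")
  row <- b[b$group == group & b$timepoint == timepoint, ]
  if (nrow(row) != 1L) {
    stop_invalid("behaviour model missing cell (%s, %s)", group, timepoint)
  }
  row
}
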