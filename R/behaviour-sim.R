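# session-split of behavioural between-subject variance (stable subject
# part persists across timepoints; session part drives within-subject change
# noise). Chosen so paired within-group t statistics at n = 50 land in the
# mid-single-digit range when the planted breath-counting gains are present.
BEH_SESSION_FRAC <- 0.42

#' Simulate a behavioural cohort for the AX-CPT and breath-counting tasks
#'
#' Generates one row per subject x timepoint with the behavioural summary
#' measures the analysis consumes: mean reaction time on correct AX targets,
#' reaction-time coefficient of variation (SD/mean), total errors as a
#' percentage of all trials, and breath-counting accuracy. Trial-level RTs
#' are drawn from a log-normal with the plan's cell mean and coefficient of
#' variation (plus stable between-subject offsets); errors are a Bernoulli
#' process over the block's trials; breath-counting accuracy is Gaussian with
#' the cell mean and between-subject SD, clipped to [0, 100].
#'
#' @param design List with `groups` (named sizes) and `timepoints`.
#' @param plan An [effect_plan()] with a behavioural model.
#' @param seed Integer seed.
#' @param n_trials AX-CPT block length (error denominator).
#' @param n_rt_trials Correct-target RTs simulated per cell.
#' @param n_breath_cycles Breath count cycles attempted per session.
#' @param return_trials Also return the trial-level RT table.
#' @return A tibble of per-cell summaries (`subject`, `group`, `timepoint`,
#'   `rt_mean_ms`, `rtcv`, `errors_pct`, `breath_accuracy`); with
#'   `return_trials = TRUE`, a list with `summary` and `trials`.
#' @export
generate_behavioural_cohort <- function(design = list(
                                          groups = c(MT = 50, CT = 31),
                                          timepoints = c("T1", "T2", "T3")
                                        ),
                                        plan = default_effect_plan(),
                                        seed = 1, n_trials = 800,
                                        n_rt_trials = 60,
                                        n_breath_cycles = 20,
                                        return_trials = FALSE) {
  groups <- design$groups
  if (any(groups < 2)) stop_invalid("group sizes must be >= 2")
  tps <- design$timepoints
  subjects <- unlist(lapply(names(groups), function(g) {
    sprintf("%s%03d", g, seq_len(groups[[g]]))
  }))
  sub_group <- rep(names(groups), groups)

  rows <- list()
  trials <- list()
  with_seed(derive_seed(seed, 17L), {
    for (si in seq_along(subjects)) {
      rt_factor <- exp(rnorm(1, 0, plan$subject_rt_sd_log) -
        plan$subject_rt_sd_log^2 / 2)
      cv_s <- max(0.02, rnorm(1, 0.14, plan$subject_cv_sd))
      err_logit_s <- rnorm(1, 0, plan$subject_error_sd_logit)
      z_breath_stable <- rnorm(1)
      for (tp in tps) {
        cell <- plan_behaviour_cell(plan, sub_group[si], tp)
        rtp <- rt_cell_params(plan, sub_group[si], tp, rt_factor, cv_s)
        rts <- rlnorm(n_rt_trials, rtp$mu, rtp$sigma)
        p_err <- stats::plogis(stats::qlogis(cell$error_prob) + err_logit_s)
        errs <- rbinom(1, n_trials, p_err)
        z_sess <- rnorm(1)
        breath <- cell$breath_mean + cell$breath_sd *
          (sqrt(1 - BEH_SESSION_FRAC) * z_breath_stable +
            sqrt(BEH_SESSION_FRAC) * z_sess)
        breath_n_ok <- round(min(100, max(0, breath)) / 100 * n_breath_cycles)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = subjects[si], group = sub_group[si], timepoint = tp,
          rt_mean_ms = mean(rts), rtcv = rtcv(rts),
          errors_pct = error_rate(errs, n_trials),
          breath_accuracy = breath_accuracy(breath_n_ok, n_breath_cycles),
          n_rt_trials = n_rt_trials, n_trials = n_trials
        )
        if (return_trials) {
          trials[[length(trials) + 1L]] <- tibble::tibble(
            subject = subjects[si], group = sub_group[si], timepoint = tp,
            trial = seq_len(n_rt_trials), rt_ms = rts, correct = TRUE,
            pair_class = "ax_target"
          )
        }
      }
    }
  })
  summary <- dplyr::bind_rows(rows)
  if (return_trials) {
    list(summary = summary, trials = dplyr::bind_rows(trials))
  } else {
    summary
  }
}

#' Write / read behavioural tables
#'
#' `write_behaviour()` writes the per-cell summary CSV (and, when supplied,
#' the trial-level CSV with columns `subject,group,timepoint,trial,rt_ms,`
#' `correct,pair_class`).
#'
#' @param summary Summary tibble from [generate_behavioural_cohort()].
#' @param dir Output directory.
#' @param trials Optional trial-level tibble.
#' @return The directory, invisibly.
#' @export
write_behaviour <- function(summary, dir, trials = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(summary, file.path(dir, "behaviour_summary.csv"))
  if (!is.null(trials)) {
    readr::write_csv(trials, file.path(dir, "behaviour_trials.csv"))
  }
  invisible(dir)
}
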