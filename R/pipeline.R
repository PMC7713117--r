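#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end synthetic
#' study run: design, effect plan, noise, preprocessing, cluster statistics
#' and the analysis matrix (which contrasts to run per stimulus class).
#' `read_pipeline_config()` loads the same structure from a YAML or JSON
#' file whose top level carries an integer `seed`.
#'
#' @param seed Integer master seed for every stage.
#' @param groups Named group sizes (default the study arms,
#'   `c(MT = 50, CT = 31)`).
#' @param timepoints Within-subject sessions.
#' @param plan `"default"`, `"null"`, or an [effect_plan()].
#' @param noise A [noise_spec()] or list of its arguments.
#' @param n_trials Trials per subject x timepoint x stimulus class.
#' @param n_channels Montage size (reduced-head layout).
#' @param sfreq,t_start,t_end Epoch grid.
#' @param preproc [preproc_config()] or list of its arguments.
#' @param stat [stat_config()] or list of its arguments.
#' @param contrasts Subset of `"time_F"`, `"group_main"`, `"pairwise"`,
#'   `"interaction"`.
#' @param stim_classes Epoch families to analyse.
#' @param preprocess Run the filtering/reference/rejection/baseline chain
#'   (`FALSE` averages the raw synthetic epochs directly).
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            groups = c(MT = 50, CT = 31),
                            timepoints = c("T1", "T2", "T3"),
                            plan = "default",
                            noise = noise_spec(),
                            n_trials = 60, n_channels = 32, sfreq = 256,
                            t_start = -0.5, t_end = 0.8,
                            preproc = preproc_config(),
                            stat = stat_config(),
                            contrasts = c(
                              "time_F", "group_main",
                              "pairwise", "interaction"
                            ),
                            stim_classes = c("cue", "target"),
                            preprocess = TRUE,
                            out_dir = tempfile("erpcluster_run_")) {
  if (is.null(names(groups)) || length(groups) != 2L) {
    stop_invalid("config field 'groups' must be two named group sizes")
  }
  if (any(groups < 2)) stop_invalid("config field 'groups': sizes must be >= 2")
  if (length(timepoints) < 2L) {
    stop_invalid("config field 'timepoints' needs >= 2 sessions")
  }
  if (is.character(plan)) {
    plan <- switch(plan,
      "default" = default_effect_plan(),
      "null" = null_effect_plan(),
      stop_invalid("config field 'plan' must be 'default', 'null' or an effect_plan")
    )
  }
  if (!inherits(plan, "effect_plan")) {
    stop_invalid("config field 'plan' must be an effect_plan")
  }
  if (is.list(noise) && !inherits(noise, "noise_spec")) {
    noise <- do.call(noise_spec, noise)
  }
  if (is.list(preproc) && !inherits(preproc, "preproc_config")) {
    preproc <- do.call(preproc_config, preproc)
  }
  if (is.list(stat) && !inherits(stat, "stat_config")) {
    stat <- do.call(stat_config, stat)
  }
  bad <- setdiff(contrasts, c("time_F", "group_main", "pairwise", "interaction"))
  if (length(bad)) {
    stop_invalid("config field 'contrasts': unsupported %s", paste(bad, collapse = ", "))
  }
  structure(
    list(
      seed = as.integer(seed), groups = groups, timepoints = timepoints,
      plan = plan, noise = noise, n_trials = n_trials,
      n_channels = as.integer(n_channels), sfreq = sfreq,
      t_start = t_start, t_end = t_end, preproc = preproc, stat = stat,
      contrasts = contrasts, stim_classes = stim_classes,
      preprocess = preprocess, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw$seed)) stop_invalid("config field 'seed' is required")
  args <- raw
  if (!is.null(args$groups)) args$groups <- unlist(args$groups)
  do.call(pipeline_config, args)
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "erpcluster_stage_error", parent = e
    )
  })
}

#' Run the full synthetic-study analysis pipeline
#'
#' Simulate, preprocess, test, correlate, report: generates the behavioural
#' cohort and subject-level ERPs for the configured design, runs the
#' configured cluster permutation contrasts per stimulus class, extracts
#' AUCs of significant clusters and correlates them with reaction time, and
#' computes the behavioural statistics (baseline group comparisons, mixed
#' ANOVAs, follow-up pairwise tests, BH-FDR). All tables are written under
#' `cfg$out_dir` as they are produced, together with a run manifest; the
#' whole run is deterministic under the configured seed.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `behaviour`, `behaviour_stats`,
#'   `cluster_results`, `correlations`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) {
    stop_invalid("run_pipeline needs a pipeline_config")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- list(groups = cfg$groups, timepoints = cfg$timepoints)
  montage <- make_montage(cfg$n_channels, "reduced-head")
  exclusions <- list()

  behaviour <- run_stage("simulate-behaviour", {
    b <- generate_behavioural_cohort(design, cfg$plan,
      seed = derive_seed(cfg$seed, 1L)
    )
    readr::write_csv(b, file.path(cfg$out_dir, "behaviour_summary.csv"))
    b
  })

  stacks <- run_stage("simulate-eeg", {
    if (cfg$preprocess) {
      epochs <- generate_eeg_epochs(design, montage, cfg$plan, cfg$noise,
        seed = derive_seed(cfg$seed, 2L), n_trials = cfg$n_trials,
        sfreq = cfg$sfreq, t_start = cfg$t_start, t_end = cfg$t_end,
        stim_classes = cfg$stim_classes
      )
      out <- list()
      for (cls in names(epochs)) {
        pp <- preprocess_epochs(epochs[[cls]], cfg$preproc)
        out[[cls]] <- pp$erps
        exclusions[[paste0("rejection_", cls)]] <- pp$rejection
        readr::write_csv(
          pp$rejection,
          file.path(cfg$out_dir, sprintf("rejection_%s.csv", cls))
        )
      }
      out
    } else {
      simulate_erp_study(design, montage, cfg$plan, cfg$noise,
        seed = derive_seed(cfg$seed, 2L), n_trials = cfg$n_trials,
        sfreq = cfg$sfreq, t_start = cfg$t_start, t_end = cfg$t_end,
        stim_classes = cfg$stim_classes
      )
    }
  })

  cluster_results <- run_stage("cluster-stats", {
    res <- list()
    tps <- cfg$timepoints
    grps <- names(cfg$groups)
    for (cls in cfg$stim_classes) {
      stack <- stacks[[cls]]
      scfg <- cfg$stat
      scfg$seed <- derive_seed(cfg$seed, 3L)
      if ("time_F" %in% cfg$contrasts && length(tps) >= 3L) {
        res[[paste0(cls, "_time_F")]] <- permutation_test(
          stack,
          design = "F-repeated", cond = "timepoint", levels = tps,
          cfg = scfg
        )
      }
      if ("group_main" %in% cfg$contrasts) {
        # subject ERPs averaged over timepoints, then groups compared
        avg <- stack_average(stack, by = c("subject", "group", "stim_class"))
        res[[paste0(cls, "_group_main")]] <- permutation_test(
          avg,
          design = "t-independent", cond = "group", levels = grps,
          cfg = scfg
        )
      }
      if ("pairwise" %in% cfg$contrasts) {
        for (g in grps) {
          sub <- stack_subset(stack, stack$info$group == g)
          for (pair in utils::combn(tps, 2, simplify = FALSE)) {
            res[[sprintf("%s_%s_%s_vs_%s", cls, g, pair[2], pair[1])]] <-
              permutation_test(sub,
                design = "t-paired", cond = "timepoint",
                levels = c(pair[2], pair[1]), cfg = scfg
              )
          }
        }
      }
      if ("interaction" %in% cfg$contrasts) {
        for (pair in utils::combn(tps, 2, simplify = FALSE)) {
          res[[sprintf("%s_interaction_%s_vs_%s", cls, pair[2], pair[1])]] <-
            interaction_contrast(stack,
              times = c(pair[1], pair[2]),
              groups = grps, cfg = scfg
            )
        }
      }
    }
    for (nm in names(res)) {
      write_cluster_report(
        res[[nm]],
        file.path(cfg$out_dir, sprintf("clusters_%s.csv", nm)),
        file.path(cfg$out_dir, sprintf("clusters_%s.json", nm))
      )
    }
    res
  })

  correlations <- run_stage("brain-behaviour", {
    aucs <- list()
    cors <- list()
    for (nm in names(cluster_results)) {
      r <- cluster_results[[nm]]
      sig <- r$clusters[r$clusters$significant, , drop = FALSE]
      if (!nrow(sig)) next
      cls <- sub("_.*$", "", nm)
      stack <- stacks[[cls]]
      win_stack <- if (!is.null(r$config$analysis_window_ms)) {
        stack_crop_idx(stack, window_to_idx(
          r$config$analysis_window_ms, stack$sfreq, stack$t_start,
          dim(stack$data)[3]
        ))
      } else {
        stack
      }
      for (i in seq_len(nrow(sig))) {
        tbl <- cluster_auc(win_stack, sig[i, ])
        tbl$contrast <- nm
        tbl$cluster_id <- sig$cluster_id[i]
        aucs[[paste(nm, i)]] <- tbl
        cor <- tryCatch(
          correlate_brain_behaviour(tbl, behaviour),
          error = function(e) NULL
        )
        if (!is.null(cor)) cors[[paste(nm, i)]] <- cor$pooled
      }
    }
    if (length(aucs)) {
      auc_tbl <- dplyr::bind_rows(aucs)
      readr::write_csv(
        dplyr::select(
          auc_tbl, dplyr::any_of(c(
            "subject", "group", "timepoint", "contrast", "cluster_id",
            "auc_uv_ms"
          ))
        ),
        file.path(cfg$out_dir, "auc_table.csv")
      )
    }
    if (length(cors)) {
      jsonlite::write_json(cors, file.path(cfg$out_dir, "correlations.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    cors
  })

  behaviour_stats <- run_stage("behaviour-stats", {
    base <- behaviour[behaviour$timepoint == cfg$timepoints[1], ]
    grps <- names(cfg$groups)
    tests <- list()
    for (dv in c("breath_accuracy", "rt_mean_ms", "rtcv", "errors_pct")) {
      tests[[paste0("baseline_", dv)]] <- independent_t(
        base[[dv]][base$group == grps[1]], base[[dv]][base$group == grps[2]],
        label = sprintf("baseline %s: %s vs %s", dv, grps[1], grps[2])
      )
    }
    anovas <- list()
    if (length(cfg$timepoints) >= 2L) {
      for (dv in c("breath_accuracy", "rt_mean_ms", "rtcv", "errors_pct")) {
        anovas[[dv]] <- tryCatch(
          dplyr::mutate(tidy(mixed_anova(behaviour, dv)), dv = dv),
          error = function(e) NULL
        )
      }
      for (g in grps) {
        for (dv in c("breath_accuracy", "errors_pct")) {
          wide <- behaviour[behaviour$group == g, ] |>
            dplyr::select("subject", "timepoint", dplyr::all_of(dv)) |>
            tidyr::pivot_wider(names_from = "timepoint", values_from = dplyr::all_of(dv))
          for (tp in setdiff(cfg$timepoints, cfg$timepoints[1])) {
            tests[[sprintf("%s_%s_%s", g, dv, tp)]] <- paired_t(
              wide[[tp]], wide[[cfg$timepoints[1]]],
              label = sprintf("%s %s: %s vs %s", g, dv, tp, cfg$timepoints[1])
            )
          }
        }
      }
    }
    pair_tbl <- dplyr::bind_rows(tests)
    fdr <- bh_fdr(pair_tbl$p_value)
    pair_tbl$p_adjusted <- fdr$p_adjusted
    pair_tbl$fdr_rejected <- fdr$rejected
    readr::write_csv(pair_tbl, file.path(cfg$out_dir, "behaviour_tests.csv"))
    anova_tbl <- dplyr::bind_rows(anovas)
    if (nrow(anova_tbl)) {
      readr::write_csv(anova_tbl, file.path(cfg$out_dir, "behaviour_anova.csv"))
    }
    list(pairwise = pair_tbl, anova = anova_tbl)
  })

  manifest <- run_stage("report", {
    m <- list(
      package_version = as.character(utils::packageVersion("erpcluster")),
      seed = cfg$seed,
      stage_seeds = list(
        behaviour = derive_seed(cfg$seed, 1L),
        eeg = derive_seed(cfg$seed, 2L),
        permutation = derive_seed(cfg$seed, 3L)
      ),
      design = list(
        groups = as.list(cfg$groups),
        timepoints = cfg$timepoints
      ),
      n_trials = cfg$n_trials,
      sfreq = cfg$sfreq,
      epoch_s = c(cfg$t_start, cfg$t_end),
      preprocess = cfg$preprocess,
      contrasts = cfg$contrasts,
      stat = cfg$stat[c(
        "alpha", "n_permutations", "min_simultaneous_channels",
        "analysis_window_ms", "mode"
      )],
      outputs = sort(list.files(cfg$out_dir)),
      exclusions = lapply(exclusions, function(x) {
        list(n_rejected = sum(x$n_rejected), n_total = sum(x$n_total))
      })
    )
    jsonlite::write_json(m, file.path(cfg$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    m
  })

  invisible(list(
    behaviour = behaviour, behaviour_stats = behaviour_stats,
    cluster_results = cluster_results, correlations = correlations,
    manifest = manifest, out_dir = cfg$out_dir
  ))
}
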