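#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster permutation result
#'
#' One row per observed cluster: sign, mass, permutation p-value, time
#' extent, channel count and cluster-masked Cohen's d.
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble (no list-columns).
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  dplyr::select(
    x$clusters, "cluster_id", "sign", "mass", "p_value",
    "t_start_ms", "t_end_ms", "n_channels", "n_points",
    "effect_size_d", "significant"
  )
}

#' Glance at a cluster permutation result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return One-row tibble with the test's bookkeeping.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    design = x$design, mode = x$mode,
    n_partitions = x$n_partitions,
    n_null = length(x$null_dist),
    threshold = x$threshold, alpha = x$config$alpha,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant %||% logical()),
    max_abs_mass = if (nrow(x$clusters)) max(abs(x$clusters$mass)) else 0
  )
}

#' @rdname mixed_anova
#' @param x A `mixed_anova` object.
#' @param ... Unused.
#' @method tidy mixed_anova
#' @export
tidy.mixed_anova <- function(x, ...) x$table

#' @rdname mixed_anova
#' @method glance mixed_anova
#' @export
glance.mixed_anova <- function(x, ...) {
  tibble::tibble(
    dv = x$dv, n_subjects = x$n_subjects, n_dropped = x$n_dropped
  )
}

#' Export a cluster report
#'
#' Writes the tidy cluster table as CSV and a JSON companion holding the
#' full member lists, the null distribution and the configuration echo.
#'
#' @param result A `cluster_result`.
#' @param path_csv,path_json Output paths (JSON optional).
#' @return `path_csv`, invisibly.
#' @export
write_cluster_report <- function(result, path_csv, path_json = NULL) {
  readr::write_csv(tidy(result), path_csv)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(
        clusters = lapply(seq_len(nrow(result$clusters)), function(i) {
          row <- result$clusters[i, ]
          list(
            cluster_id = row$cluster_id, sign = row$sign, mass = row$mass,
            p_value = row$p_value, effect_size_d = row$effect_size_d,
            members = row$members[[1]][, c("channel", "sample", "time_ms")]
          )
        }),
        null_dist = result$null_dist,
        config = result$config[setdiff(names(result$config), "seed")],
        seed = result$config$seed,
        mode = result$mode, n_partitions = result$n_partitions,
        threshold = result$threshold,
        adjacency = result$adjacency_info
      ),
      path_json,
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
  }
  invisible(path_csv)
}
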