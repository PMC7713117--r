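#' Plot grand-average ERPs by condition
#'
#' Channel-averaged (or single-channel) ERP waveforms per condition cell,
#' with optional shaded cluster extents.
#'
#' @param stack An [erp_stack()].
#' @param colour Metadata column mapped to colour (default `"timepoint"`).
#' @param channels Channel labels to average over (default: all).
#' @param clusters Optional tidy cluster tibble whose significant rows are
#'   shaded.
#' @return A ggplot object.
#' @export
plot_erp <- function(stack, colour = "timepoint", channels = NULL,
                     clusters = NULL) {
  long <- as_tibble(stack)
  if (!is.null(channels)) {
    long <- dplyr::filter(long, .data$channel %in% channels)
  }
  df <- long |>
    dplyr::group_by(
      .data$time_ms,
      dplyr::across(dplyr::all_of(colour))
    ) |>
    dplyr::summarise(uv = mean(.data$uv), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    .data$time_ms, .data$uv,
    colour = .data[[colour]]
  )) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (ms)", y = "amplitude (µV)",
      colour = colour
    ) +
    ggplot2::theme_minimal()
  if (!is.null(clusters) && nrow(clusters)) {
    sig <- clusters[clusters$significant %||% rep(TRUE, nrow(clusters)), ]
    if (nrow(sig)) {
      p <- p + ggplot2::annotate("rect",
        xmin = sig$t_start_ms, xmax = sig$t_end_ms,
        ymin = -Inf, ymax = Inf, alpha = 0.15
      )
    }
  }
  p
}

#' @method autoplot erp_stack
#' @export
autoplot.erp_stack <- function(object, ...) plot_erp(object, ...)

#' Plot a cluster permutation result
#'
#' Raster of the observed statistic map with cluster members outlined, or
#' the null distribution of the maximum cluster mass with the observed
#' cluster masses marked.
#'
#' @param object A `cluster_result`.
#' @param type `"map"` or `"null"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, type = c("map", "null"), ...) {
  type <- match.arg(type)
  if (type == "null") {
    df <- tibble::tibble(max_mass = object$null_dist)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$max_mass)) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::labs(
        x = "max |cluster mass| per partition",
        y = "partitions"
      ) +
      ggplot2::theme_minimal()
    if (nrow(object$clusters)) {
      p <- p + ggplot2::geom_vline(
        xintercept = abs(object$clusters$mass),
        linetype = 2
      )
    }
    return(p)
  }
  map <- object$stat_map
  times_ms <- sample_times(ncol(map$stat), map$sfreq, map$t_start) * 1000
  df <- tidyr::expand_grid(
    channel = factor(rownames(map$stat), levels = rownames(map$stat)),
    time_ms = times_ms
  )
  df$stat <- as.vector(t(map$stat))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    .data$time_ms, .data$channel,
    fill = .data$stat
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (ms)", y = NULL, fill = map$kind) +
    ggplot2::theme_minimal()
  if (nrow(object$clusters)) {
    mem <- dplyr::bind_rows(object$clusters$members)
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(mem,
        channel = factor(.data$channel, levels = rownames(map$stat))
      ),
      ggplot2::aes(.data$time_ms, .data$channel),
      inherit.aes = FALSE, size = 0.3
    )
  }
  p
}

#' Scalp topography of a montage, optionally highlighting cluster channels
#'
#' @param montage A `montage`.
#' @param highlight Channel labels to emphasise.
#' @return A ggplot object.
#' @export
plot_montage <- function(montage, highlight = NULL) {
  df <- montage$channels
  df$highlight <- df$channel %in% (highlight %||% character())
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel),
      size = 2, vjust = -1
    ) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "red"), guide = "none"
    ) +
    ggplot2::theme_void()
}
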