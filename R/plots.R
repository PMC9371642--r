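#' Plot benchmark power across procedures
#'
#' Bar chart of mean power per procedure, faceted by group size, in the
#' focal-to-broad procedure order.
#'
#' @param object A `benchmark_grid` (or the `summary` tibble of a
#'   `benchmark_result`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_grid
#' @export
autoplot.benchmark_grid <- function(object, ...) {
  df <- dplyr::filter(object, .data$contrast == "real")
  df$procedure <- factor(df$procedure, levels = connbench_procedures())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$procedure,
                                   y = .data$mean_power,
                                   fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$variant),
                        cols = ggplot2::vars(.data$n),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "mean power",
                  title = "Power by scale of inference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname autoplot.benchmark_grid
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- dplyr::select(object$summary, -"tpr")
  df$procedure <- factor(df$procedure, levels = connbench_procedures())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$procedure,
                                   y = .data$mean_power,
                                   fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant)) +
    ggplot2::labs(x = NULL, y = "mean power") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot power against ground-truth effect size
#'
#' @param curve Output of [power_by_effect_size()].
#' @param procedure Optional label for the plot title.
#' @return A ggplot object.
#' @export
plot_power_by_effect_size <- function(curve, procedure = NULL) {
  mid <- (curve$bin_lo + curve$bin_hi) / 2
  df <- dplyr::mutate(curve, mid = mid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$mean_power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_edges), alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "|d| (ground-truth effect size)", y = "mean power",
                  title = procedure %||% "Power by effect size") +
    ggplot2::theme_minimal()
}

#' Plot the ground-truth effect-size distributions
#'
#' Histograms of edge- and network-level effect sizes.
#'
#' @param object A `ground_truth_map`.
#' @param bins Histogram bins for the edge level (network level uses half).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ground_truth_map
#' @export
autoplot.ground_truth_map <- function(object, bins = 40L, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(level = "edge", d = object$d_edge),
    tibble::tibble(level = "network", d = object$d_network)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$level), scales = "free") +
    ggplot2::labs(x = "Cohen's d (task - rest)", y = "count",
                  title = sprintf("Ground-truth effects (%s variant)",
                                  object$variant)) +
    ggplot2::theme_minimal()
}
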