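# ggplot2 views of the framework's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Pareto front over two criteria
#'
#' @param object A `pareto_front` (built from a data frame so combination
#'   labels are available).
#' @param x_metric,y_metric Criteria columns to display; default the first
#'   two criteria columns.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pareto_front <- function(object, x_metric = NULL, y_metric = NULL,
                                  ...) {
  crit <- colnames(object$criteria)
  x_metric <- x_metric %||% crit[1]
  y_metric <- y_metric %||% crit[2]
  df <- as_tibble(abs(object$criteria))  # undo direction alignment for display
  df$on_front <- seq_len(nrow(df)) %in% object$front
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x_metric]],
    y = .data[[y_metric]], colour = .data$on_front)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02",
      `FALSE` = "grey60"), name = "Pareto front") +
    ggplot2::theme_minimal()
}

#' Plot per-resample clustering stability
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot (Jaccard and ARI distributions over resamples).
#' @export
autoplot.stability_report <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("jaccard", "ari"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "similarity to full-data reference") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pathway embedding
#'
#' @param object A `pathway_embedding`.
#' @param ... Unused.
#' @return A ggplot tile heatmap (pathways x samples, adjusted scores).
#' @export
autoplot.pathway_embedding <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$sample_id,
    y = .data$pathway, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
      high = "#b2182b", name = "NES x -log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Summary plot of aggregated benchmark metrics
#'
#' @param aggregated Output of [aggregate_metrics()].
#' @param metrics Metrics to display (default the five-criterion set).
#' @return A ggplot: one facet per metric, mean +/- SD per combination.
#' @export
plot_metric_summary <- function(aggregated,
                                metrics = c("silhouette",
                                  "stability_jaccard", "batch_inverse",
                                  "module_score", "survival_nlp")) {
  df <- aggregated |>
    dplyr::filter(.data$metric %in% metrics) |>
    dplyr::mutate(combo = paste(.data$embedding, .data$clusterer,
      .data$k, sep = "/"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combo, y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$sd,
      ymax = .data$value + .data$sd), linewidth = 0.3, size = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean over resamples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
      ggplot2::element_text(angle = 60, hjust = 1))
}
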