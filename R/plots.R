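# ggplot2 views of the main result types.

#' Plot the polarity composition of a graph's edges
#'
#' @param graph A `kg_graph`.
#' @return A ggplot bar chart of unique-edge counts per polarity class,
#'   labelled with percentage shares.
#' @export
plot_polarity <- function(graph) {
  df <- polarity_summary(graph)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$polarity, y = .data$n,
                                   fill = .data$polarity)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$share, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "unique edges",
                  title = "Edge polarity composition") +
    ggplot2::theme_minimal()
}

#' Plot the degree distribution
#'
#' @param graph A `kg_graph`.
#' @param log_log Use log10 axes (default TRUE), the usual view for
#'   right-skewed biological networks.
#' @return A ggplot of the degree frequency distribution.
#' @export
plot_degree_distribution <- function(graph, log_log = TRUE) {
  df <- degree_table(graph) |> count(.data$degree)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "degree", y = "entities",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
  if (log_log) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Plot top hubs
#'
#' @param graph A `kg_graph`.
#' @param k Number of hubs.
#' @param measure `"weighted_degree"` or `"degree"`.
#' @return A ggplot horizontal bar chart coloured by entity category.
#' @export
plot_hubs <- function(graph, k = 10,
                      measure = c("weighted_degree", "degree")) {
  measure <- match.arg(measure)
  df <- top_hubs(graph, k, measure) |>
    mutate(label = stats::reorder(.data$label, .data[[measure]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[measure]], y = .data$label,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = measure, y = NULL, title = "Top hubs") +
    ggplot2::theme_minimal()
}

#' Heatmap of the category-connectivity matrix
#'
#' @param graph A `kg_graph`.
#' @param normalization `"max"` or `"row"`.
#' @return A ggplot tile heatmap.
#' @export
plot_category_connectivity <- function(graph,
                                       normalization = c("max", "row")) {
  normalization <- match.arg(normalization)
  mat <- category_connectivity(graph, normalization)
  df <- as_tibble(mat, rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Category connectivity (normalized)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot coverage benchmark results
#'
#' @param bench A `kg_benchmark` from [benchmark_summary()].
#' @return A ggplot bar chart of per-pathway entity coverage with the
#'   unweighted mean as a dashed line.
#' @export
plot_coverage <- function(bench) {
  df <- bench$table
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pathway_id,
                                                      .data$C_entity),
                                   y = .data$C_entity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = bench$mean_entity_coverage,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "entity coverage (%)",
                  title = "Pathway coverage benchmark") +
    ggplot2::theme_minimal()
}

#' @method autoplot kg_graph
#' @export
autoplot.kg_graph <- function(object, ...) plot_polarity(object)

#' @method autoplot kg_benchmark
#' @export
autoplot.kg_benchmark <- function(object, ...) plot_coverage(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
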