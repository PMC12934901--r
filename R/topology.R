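# Network topology: degrees, hubs, clustering, density, per-category
# summaries and the category-connectivity matrix.
#
# Degree and weighted degree are computed on the directed multigraph (every
# unique edge counts once, in + out); clustering and density are classical
# undirected measures, so they are computed on the undirected simple
# projection in which parallel edges of different relation types collapse
# into one link and self-loops vanish.

#' Per-node degree and weighted degree
#'
#' Degree is the number of incident edges (incoming plus outgoing) on the
#' directed multigraph; weighted degree is the sum of the incident edges'
#' evidence weights. Entities are ranked by weighted degree to surface hubs.
#'
#' @param graph A `kg_graph`.
#' @return Tibble (label, category, degree, weighted_degree), sorted by
#'   weighted degree descending, label ascending.
#' @export
degree_table <- function(graph) {
  incident <- bind_rows(
    graph$edges |> select(label = "source", "weight"),
    graph$edges |> select(label = "target", "weight")
  )
  deg <- incident |>
    group_by(.data$label) |>
    summarise(degree = n(), weighted_degree = sum(.data$weight),
              .groups = "drop")
  graph$nodes |>
    select("label", "category") |>
    left_join(deg, by = "label") |>
    mutate(
      degree = ifelse(is.na(.data$degree), 0L, .data$degree),
      weighted_degree = ifelse(is.na(.data$weighted_degree), 0,
                               .data$weighted_degree)
    ) |>
    arrange(desc(.data$weighted_degree), .data$label)
}

#' Top network hubs
#'
#' @param graph A `kg_graph`.
#' @param k Number of hubs to return (>= 1); if larger than the node count,
#'   all nodes are returned.
#' @param measure Ranking measure: `"weighted_degree"` (default) or
#'   `"degree"`.
#' @return Tibble of the top-k nodes in stable descending order; ties are
#'   broken lexicographically by label.
#' @export
top_hubs <- function(graph, k = 10,
                     measure = c("weighted_degree", "degree")) {
  if (k < 1) abort("k must be >= 1")
  measure <- match.arg(measure)
  degree_table(graph) |>
    arrange(desc(.data[[measure]]), .data$label) |>
    head(min(k, nrow(graph$nodes)))
}

undirected_simple_pairs <- function(graph) {
  e <- graph$edges |> filter(.data$source != .data$target)
  if (nrow(e) == 0) {
    return(tibble(a = character(), b = character()))
  }
  tibble(
    a = pmin(e$source, e$target),
    b = pmax(e$source, e$target)
  ) |> distinct()
}

#' Mean local clustering coefficient and network density
#'
#' Both statistics are computed on the undirected simple projection of the
#' graph: parallel edges of different relation types collapse into one
#' link. The mean local clustering coefficient averages over *all* nodes,
#' with degree-<2 nodes contributing 0; density is the ratio of observed
#' links to all N(N-1)/2 possible links.
#'
#' @param graph A `kg_graph` with at least 2 nodes.
#' @return Tibble with columns `clustering` and `density`, both in [0, 1].
#' @export
clustering_and_density <- function(graph) {
  n <- nrow(graph$nodes)
  if (n < 2) abort("density is undefined for graphs with fewer than 2 nodes")
  pairs <- undirected_simple_pairs(graph)
  g <- igraph::graph_from_data_frame(
    pairs, directed = FALSE,
    vertices = graph$nodes$label
  )
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  tibble(
    clustering = mean(cc),
    density = nrow(pairs) / (n * (n - 1) / 2)
  )
}

#' Per-category degree summaries
#'
#' @param graph A `kg_graph`.
#' @return Tibble (category, n_nodes, min, median, mean, max of degree).
#' @export
category_degree_summary <- function(graph) {
  degree_table(graph) |>
    group_by(.data$category) |>
    summarise(
      n_nodes = n(),
      min = min(.data$degree),
      median = median(.data$degree),
      mean = mean(.data$degree),
      max = max(.data$degree),
      .groups = "drop"
    ) |>
    arrange(desc(.data$mean))
}

#' Category-connectivity matrix
#'
#' Cell (a, b) counts edges from a source of category `a` to a target of
#' category `b`; the matrix is then symmetrized by adding its transpose and
#' normalized, by the global maximum (default) or by row sums.
#'
#' @param graph A `kg_graph`.
#' @param normalization `"max"` (default) or `"row"`.
#' @return Square numeric matrix with category dimnames.
#' @export
category_connectivity <- function(graph, normalization = c("max", "row")) {
  normalization <- match.arg(normalization)
  cats <- sort(unique(stats::na.omit(graph$nodes$category)))
  mat <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  if (nrow(graph$edges) > 0 && length(cats) > 0) {
    node_cat <- setNames(graph$nodes$category, graph$nodes$label)
    sc <- node_cat[graph$edges$source]
    tc <- node_cat[graph$edges$target]
    ok <- !is.na(sc) & !is.na(tc)
    counts <- table(factor(sc[ok], levels = cats),
                    factor(tc[ok], levels = cats))
    mat <- unclass(counts) + t(unclass(counts))
    dimnames(mat) <- list(cats, cats)
  }
  if (normalization == "max") {
    m <- if (length(mat) > 0) max(mat) else 0
    if (m > 0) mat <- mat / m
  } else {
    rs <- rowSums(mat)
    nz <- rs > 0
    mat[nz, ] <- mat[nz, , drop = FALSE] / rs[nz]
  }
  mat
}

#' Full topology report
#'
#' Bundles the per-node degree table, top hubs, mean local clustering,
#' density, per-category degree summaries, and the category-connectivity
#' matrix. Clustering/density use the undirected simple projection
#' (unweighted); degrees and hubs use the directed multigraph — stated here
#' because the two conventions differ.
#'
#' @param graph A `kg_graph`.
#' @param k Number of hubs.
#' @param measure Hub ranking measure.
#' @param normalization Connectivity-matrix normalization.
#' @return A `kg_topology_report` list.
#' @export
topology_report <- function(graph, k = 10,
                            measure = c("weighted_degree", "degree"),
                            normalization = c("max", "row")) {
  measure <- match.arg(measure)
  cd <- if (nrow(graph$nodes) >= 2) clustering_and_density(graph) else
    tibble(clustering = NA_real_, density = NA_real_)
  structure(
    list(
      degrees = degree_table(graph),
      hubs = top_hubs(graph, k, measure),
      clustering = cd$clustering,
      density = cd$density,
      category_summary = category_degree_summary(graph),
      connectivity = category_connectivity(graph, normalization),
      conventions = paste(
        "degrees: directed multigraph (in+out);",
        "clustering/density: undirected simple projection, unweighted;",
        "degree<2 nodes contribute clustering 0"
      )
    ),
    class = "kg_topology_report"
  )
}

#' @export
print.kg_topology_report <- function(x, ...) {
  cat("<kg_topology_report>\n")
  cat("  clustering:", format(x$clustering, digits = 3),
      " density:", format(x$density, digits = 3), "\n")
  cat("  top hubs:\n")
  print(head(x$hubs, 5))
  invisible(x)
}

#' Glance at a topology report
#'
#' @param x A `kg_topology_report`.
#' @param ... Unused.
#' @return One-row tibble: nodes, clustering, density, top hub label and
#'   its degree.
#' @method glance kg_topology_report
#' @export
glance.kg_topology_report <- function(x, ...) {
  tibble(
    nodes = nrow(x$degrees),
    clustering = x$clustering,
    density = x$density,
    top_hub = if (nrow(x$hubs)) x$hubs$label[1] else NA_character_,
    top_hub_degree = if (nrow(x$hubs)) x$hubs$degree[1] else NA_integer_
  )
}

#' Write a topology report to disk
#'
#' JSON summary plus TSV tables (degrees, hubs, category summary) and the
#' connectivity matrix as TSV with category headers.
#'
#' @param report A `kg_topology_report`.
#' @param dir Output directory.
#' @param meta Optional named list merged into the JSON summary.
#' @return Invisibly, `dir`.
#' @export
write_topology_report <- function(report, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$degrees, file.path(dir, "degrees.tsv"))
  readr::write_tsv(report$hubs, file.path(dir, "hubs.tsv"))
  readr::write_tsv(report$category_summary,
                   file.path(dir, "category_degree_summary.tsv"))
  conn <- as_tibble(report$connectivity, rownames = "category")
  readr::write_tsv(conn, file.path(dir, "category_connectivity.tsv"))
  jsonlite::write_json(
    c(list(clustering = report$clustering, density = report$density,
           conventions = report$conventions), meta),
    file.path(dir, "topology.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
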