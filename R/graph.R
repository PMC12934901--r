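# Knowledge-graph assembly: aggregation of relation instances into unique
# polarity-weighted edges, evidence weighting W = ln(F + 1) * P, pruning of
# relation-free entities, and graph exports.

#' Composite evidence weight of an edge
#'
#' The weight of a (source, target, relation-type) triple supported by `F`
#' unique abstracts with polarity class `p` is
#' \deqn{W = \ln(F + 1) \times P(p)}
#' where the natural logarithm damps the influence of high-frequency
#' associations and `P` is the polarity multiplier (by default 1.2 for
#' beneficial, 1.1 for harmful, 1.0 for neutral). W is strictly increasing
#' in `F` for fixed polarity; an edge cannot exist without evidence, so
#' `frequency < 1` is an error.
#'
#' @param frequency Integer vector of unique-document frequencies (>= 1).
#' @param polarity Character vector in beneficial/harmful/neutral (recycled).
#' @param pw A [polarity_weights()] object.
#' @return Numeric vector of weights.
#' @examples
#' compute_edge_weight(9, "neutral")            # ln(10)      = 2.303
#' compute_edge_weight(4, "beneficial")         # ln(5) * 1.2 = 1.931
#' compute_edge_weight(1, "neutral")            # ln(2)       = 0.693
#' @export
compute_edge_weight <- function(frequency, polarity, pw = polarity_weights()) {
  if (length(frequency) == 0) return(numeric())
  if (any(is.na(frequency)) || any(frequency < 1) ||
      any(frequency != floor(frequency))) {
    abort("frequency must be a positive integer: an edge needs evidence")
  }
  bad <- setdiff(unique(polarity), names(pw))
  if (length(bad) > 0) {
    abort(paste0("unknown polarity class: ", paste(bad, collapse = ", ")))
  }
  log(frequency + 1) * unname(pw[polarity])
}

resolve_polarity <- function(polarities) {
  # majority over merged instances; ties resolve to neutral
  tab <- table(polarities)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) "neutral" else top
}

#' Aggregate relation instances into unique edges
#'
#' Groups all relation instances of a consolidated corpus by the
#' (source label, target label, relation type) triple. For each triple the
#' evidence frequency F is the number of *distinct* supporting documents
#' (not instances); the total instance count is retained for provenance.
#' When merged instances disagree on polarity, the majority class wins and
#' ties resolve to neutral (the conflict is recorded). Relations whose
#' endpoint label is empty are skipped with a warning; self-loops (source
#' label equal to target label after consolidation) are dropped with a
#' warning.
#'
#' @param corpus A `kg_corpus` whose mentions carry a `label` column
#'   (see [apply_consolidation()]).
#' @param schema A `kg_schema`.
#' @return Tibble of edges: source, target, relation_type, polarity,
#'   frequency, instance_count, supporting_docs (list column of sorted doc
#'   ids), polarity_conflict (logical). Weights are not yet set.
#' @export
aggregate_edges <- function(corpus, schema = kg_schema()) {
  if (!"label" %in% names(corpus$mentions)) {
    abort("corpus mentions have no `label` column; run apply_consolidation() first")
  }
  r <- corpus$relations
  if (nrow(r) == 0) return(empty_edges())
  labels <- corpus$mentions |>
    select("doc_id", "mention_id", "label")
  inst <- r |>
    left_join(rename(labels, source = "label"),
              by = c(doc_id = "doc_id", source_mention = "mention_id")) |>
    left_join(rename(labels, target = "label"),
              by = c(doc_id = "doc_id", target_mention = "mention_id"))
  empty <- is.na(inst$source) | is.na(inst$target) |
    !nzchar(inst$source) | !nzchar(inst$target)
  if (any(empty)) {
    warn(paste0("skipping ", sum(empty), " relation(s) with empty endpoint label"))
    inst <- inst[!empty, , drop = FALSE]
  }
  loops <- inst$source == inst$target
  if (any(loops)) {
    warn(paste0("dropping ", sum(loops), " self-loop relation(s)"))
    inst <- inst[!loops, , drop = FALSE]
  }
  if (nrow(inst) == 0) return(empty_edges())
  inst |>
    group_by(.data$source, .data$target, .data$relation_type) |>
    summarise(
      polarity_conflict = n_distinct(.data$polarity) > 1,
      polarity = resolve_polarity(.data$polarity),
      frequency = n_distinct(.data$doc_id),
      instance_count = n(),
      supporting_docs = list(sort(unique(.data$doc_id))),
      .groups = "drop"
    ) |>
    relocate("polarity", .before = "polarity_conflict") |>
    arrange(.data$source, .data$target, .data$relation_type)
}

empty_edges <- function() {
  tibble(
    source = character(), target = character(), relation_type = character(),
    polarity = character(), polarity_conflict = logical(),
    frequency = integer(), instance_count = integer(),
    supporting_docs = list()
  )
}

#' Build the knowledge graph from an annotated corpus
#'
#' Runs the full construction pipeline: synonym consolidation, aggregation
#' of relation instances into unique (source, target, type) edges, evidence
#' weighting W = ln(F+1) * P, and pruning of entities that participate in
#' no relationship edge. The build log records counts at every stage.
#'
#' @param corpus A `kg_corpus`.
#' @param map A `kg_synonym_map` (identity map by default).
#' @param schema A `kg_schema`.
#' @param pw Polarity multipliers.
#' @return A `kg_graph`: list with `nodes` (label, category, n_mentions,
#'   tibble), `edges` (weighted edge tibble), `directed = TRUE`, and
#'   `log` (stage counts plus the consolidation report).
#' @examples
#' doc <- parse_standoff(c(
#'   "T1\tnutrition 0 5\tfiber",
#'   "T2\tmetabolite 10 18\tbutyrate",
#'   "R1\tincreases Arg1:T1 Arg2:T2"
#' ), doc_id = "d1")
#' g <- build_graph(doc)
#' g$edges$weight  # ln(2) * 1.2
#' @export
build_graph <- function(corpus, map = synonym_map(), schema = kg_schema(),
                        pw = schema$multipliers) {
  consolidated <- apply_consolidation(corpus, map)
  edges <- aggregate_edges(consolidated, schema)
  edges$weight <- compute_edge_weight(edges$frequency, edges$polarity, pw)
  edges <- relocate(edges, "weight", .after = "frequency")

  m <- consolidated$mentions
  entity_labels <- if (nrow(m) > 0) unique(m$label) else character()
  connected <- unique(c(edges$source, edges$target))
  nodes <- if (nrow(m) == 0) {
    tibble(label = character(), category = character(), n_mentions = integer())
  } else {
    m |>
      filter(.data$label %in% connected) |>
      group_by(.data$label) |>
      summarise(
        category = names(sort(table(.data$category), decreasing = TRUE))[1],
        n_mentions = n(),
        .groups = "drop"
      ) |>
      arrange(.data$label)
  }
  # endpoints can exist without a surviving mention row only in synthetic
  # edge injection; keep the graph closed regardless
  orphan <- setdiff(connected, nodes$label)
  if (length(orphan) > 0) {
    nodes <- bind_rows(nodes, tibble(
      label = orphan, category = NA_character_, n_mentions = 0L
    )) |> arrange(.data$label)
  }

  structure(
    list(
      nodes = nodes,
      edges = edges,
      directed = TRUE,
      log = list(
        documents = n_distinct(c(corpus$mentions$doc_id,
                                 corpus$relations$doc_id)),
        mentions = nrow(corpus$mentions),
        relation_instances = nrow(corpus$relations),
        entities_before_pruning = length(entity_labels),
        entities_after_pruning = nrow(nodes),
        unique_edges = nrow(edges),
        polarity_conflicts = sum(edges$polarity_conflict),
        consolidation = unclass(attr(consolidated, "consolidation"))
      )
    ),
    class = "kg_graph"
  )
}

#' @export
print.kg_graph <- function(x, ...) {
  cat("<kg_graph>", nrow(x$nodes), "entities,", nrow(x$edges),
      "weighted edges (directed)\n")
  invisible(x)
}

#' Tidy a knowledge graph into its edge table
#'
#' @param x A `kg_graph`.
#' @param ... Unused.
#' @return The edge tibble (source, target, relation_type, polarity,
#'   frequency, weight, instance_count, supporting_docs).
#' @method tidy kg_graph
#' @export
tidy.kg_graph <- function(x, ...) x$edges

#' One-row summary of a knowledge graph
#'
#' @param x A `kg_graph`.
#' @param ... Unused.
#' @return One-row tibble: nodes, edges, documents, relation instances,
#'   mean and max edge weight.
#' @method glance kg_graph
#' @export
glance.kg_graph <- function(x, ...) {
  tibble(
    nodes = nrow(x$nodes),
    edges = nrow(x$edges),
    documents = x$log$documents,
    relation_instances = x$log$relation_instances,
    mean_weight = if (nrow(x$edges)) mean(x$edges$weight) else NA_real_,
    max_weight = if (nrow(x$edges)) max(x$edges$weight) else NA_real_
  )
}

#' Polarity composition of the graph's edges
#'
#' Shares are computed over unique edges and reported in percent to one
#' decimal.
#'
#' @param graph A `kg_graph`.
#' @return Tibble (polarity, n, share) covering all three classes.
#' @export
polarity_summary <- function(graph) {
  counts <- table(factor(graph$edges$polarity, levels = KG_POLARITIES))
  total <- sum(counts)
  tibble(
    polarity = KG_POLARITIES,
    n = as.integer(counts),
    share = if (total == 0) rep(0, 3) else
      round_half_up(as.integer(counts) / total * 100, 1)
  )
}

#' Polarity shares from per-type edge counts
#'
#' Folds a named vector of per-relation-type unique-edge counts into the
#' three polarity classes using the schema's type-to-polarity mapping.
#' Useful for polarity bookkeeping when only a per-type breakdown is
#' available.
#'
#' @param type_counts Named integer vector (names are relation types).
#' @param schema A `kg_schema`.
#' @return Tibble (polarity, n, share in percent, 1 decimal) plus an
#'   attribute `total` with the summed edge count.
#' @examples
#' polarity_shares(c(benefits = 720, increases = 381, harms = 117,
#'                   reduces = 402, inhibits = 164, associated_with = 1588,
#'                   affects = 742, causes = 361, regulates = 153,
#'                   modifies = 74, maintains = 57, assists = 13))
#' @export
polarity_shares <- function(type_counts, schema = kg_schema()) {
  bad <- setdiff(names(type_counts), schema$relation_types)
  if (length(bad) > 0) {
    abort(paste0("unknown relation types: ", paste(bad, collapse = ", ")))
  }
  pol <- default_polarity(names(type_counts), schema)
  agg <- tapply(as.integer(type_counts), factor(pol, levels = KG_POLARITIES),
                sum, default = 0L)
  total <- sum(agg)
  out <- tibble(
    polarity = KG_POLARITIES,
    n = as.integer(agg),
    share = if (total == 0) rep(0, 3) else
      round_half_up(as.integer(agg) / total * 100, 1)
  )
  attr(out, "total") <- total
  out
}

# ---- exports ---------------------------------------------------------------

#' Convert a knowledge graph to an igraph object
#'
#' @param graph A `kg_graph`.
#' @param directed Keep edge direction (default TRUE).
#' @param simplify Collapse parallel edges and drop loops (used for the
#'   clustering/density projection).
#' @return An igraph graph with node attribute `category` and edge
#'   attributes `relation_type`, `polarity`, `frequency`, `weight`.
#' @export
as_igraph <- function(graph, directed = TRUE, simplify = FALSE) {
  edges <- graph$edges |>
    select("source", "target", "relation_type", "polarity",
           "frequency", "weight")
  vertices <- graph$nodes |> select("label", "category", "n_mentions")
  g <- igraph::graph_from_data_frame(edges, directed = directed,
                                     vertices = vertices)
  if (simplify) {
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = "first")
  }
  g
}

#' Write graph artifacts: node and edge TSVs
#'
#' Nodes TSV has label, category, degree, weighted_degree; edges TSV has
#' source, target, relation_type, polarity, frequency, weight, instance
#' count and ';'-joined supporting doc ids. Deterministic row order.
#'
#' @param graph A `kg_graph`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_graph_tables <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  deg <- degree_table(graph)
  nodes_path <- file.path(dir, "nodes.tsv")
  edges_path <- file.path(dir, "edges.tsv")
  readr::write_tsv(deg, nodes_path)
  edges <- graph$edges |>
    mutate(doc_ids = purrr::map_chr(.data$supporting_docs, paste,
                                    collapse = ";")) |>
    select("source", "target", "relation_type", "polarity", "frequency",
           "weight", "instance_count", "doc_ids")
  readr::write_tsv(edges, edges_path)
  invisible(c(nodes_path, edges_path))
}

#' Read graph artifacts written by [write_graph_tables()]
#'
#' @param dir Directory containing nodes.tsv and edges.tsv.
#' @return A `kg_graph` (build log restored from build_log.json if present).
#' @export
read_graph_tables <- function(dir) {
  nodes_path <- file.path(dir, "nodes.tsv")
  edges_path <- file.path(dir, "edges.tsv")
  if (!file.exists(nodes_path) || !file.exists(edges_path)) {
    abort(paste0("no graph artifact in ", dir,
                 ": run the build step first (cmd_build)"))
  }
  nodes <- readr::read_tsv(nodes_path, col_types = "ccid") |>
    select(label = "label", category = "category") |>
    mutate(n_mentions = NA_integer_)
  edges <- readr::read_tsv(
    edges_path,
    col_types = readr::cols(
      source = "c", target = "c", relation_type = "c", polarity = "c",
      frequency = "i", weight = "d", instance_count = "i", doc_ids = "c"
    )
  ) |>
    mutate(
      supporting_docs = purrr::map(.data$doc_ids, ~ strsplit(.x, ";")[[1]]),
      polarity_conflict = NA
    ) |>
    select("source", "target", "relation_type", "polarity",
           "polarity_conflict", "frequency", "weight", "instance_count",
           "supporting_docs")
  log_path <- file.path(dir, "build_log.json")
  build_log <- if (file.exists(log_path)) jsonlite::fromJSON(log_path) else list()
  structure(
    list(nodes = nodes, edges = edges, directed = TRUE, log = build_log),
    class = "kg_graph"
  )
}

#' Export the graph as GraphML
#'
#' @param graph A `kg_graph`.
#' @param path Output .graphml path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  # igraph cannot serialize NA character attributes to GraphML
  cat_attr <- igraph::vertex_attr(g, "category")
  cat_attr[is.na(cat_attr)] <- ""
  g <- igraph::set_vertex_attr(g, "category", value = cat_attr)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
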