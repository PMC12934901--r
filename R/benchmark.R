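# External validation: entity and edge coverage of the graph against
# curated pathway marker sets (e.g. compiled from KEGG or Reactome pathway
# definitions).
#
#   C_entity = M_detected / M_total  x 100%
#   C_edge   = R_found   / R_expected x 100%
#
# Marker matching reuses the whole-word case-insensitive keyword rule, with
# optional per-marker synonym lists, because database labels (e.g.
# "butanoate") rarely match literature surface forms ("butyrate") verbatim.

#' Construct a marker set
#'
#' @param pathway_id Short identifier.
#' @param external_ref External database pathway reference text, e.g.
#'   `"KEGG map00650"`.
#' @param markers Non-empty character vector of marker labels, or a named
#'   list `marker = character vector of synonyms`.
#' @param expected_edges Optional tibble (source, target) of expected
#'   directed relationships between markers.
#' @param name Human-readable name.
#' @return A `kg_marker_set`.
#' @export
marker_set <- function(pathway_id, external_ref = "", markers,
                       expected_edges = NULL, name = pathway_id) {
  if (is.character(markers)) {
    markers <- setNames(as.list(markers), markers)
  }
  if (length(markers) == 0) abort("marker set must be non-empty")
  markers <- purrr::map(markers, as.character)
  if (!is.null(expected_edges)) {
    expected_edges <- as_tibble(expected_edges)[, c("source", "target")]
    bad <- setdiff(unique(c(expected_edges$source, expected_edges$target)),
                   names(markers))
    if (length(bad) > 0) {
      abort(paste0("expected-edge endpoints not in the marker list: ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(pathway_id = pathway_id, name = name, external_ref = external_ref,
         markers = markers, expected_edges = expected_edges),
    class = "kg_marker_set"
  )
}

#' Read marker sets from JSON
#'
#' Array of objects with `pathway_id`, `external_ref`, `markers` (object
#' mapping marker label to synonym array, or plain array), and optionally
#' `expected_edges` (array of {source, target}).
#'
#' @param path JSON file path.
#' @return List of `kg_marker_set`.
#' @export
read_marker_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("marker-set file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  purrr::map(raw, function(ms) {
    markers <- ms$markers
    if (is.list(markers) && !is.null(names(markers))) {
      markers <- purrr::map(markers, unlist)
    } else {
      markers <- unlist(markers)
    }
    marker_set(
      pathway_id = ms$pathway_id,
      name = ms$name %||% ms$pathway_id,
      external_ref = ms$external_ref %||% "",
      markers = markers,
      expected_edges = if (!is.null(ms$expected_edges)) {
        bind_rows(purrr::map(ms$expected_edges, as_tibble))
      }
    )
  })
}

marker_hit <- function(graph, marker, synonyms) {
  any(matches_keyword(graph$nodes$label, unique(c(marker, synonyms))))
}

#' Entity coverage of a marker set
#'
#' A marker is detected when any graph node matches the marker label or one
#' of its synonyms under the whole-word case-insensitive rule. Coverage is
#' reported in percent, one decimal, half-up.
#'
#' @param graph A `kg_graph`.
#' @param ms A `kg_marker_set`.
#' @return A `kg_coverage` list: pathway_id, external_ref, M_detected,
#'   M_total, C_entity, detected/missing marker vectors (edge fields NA).
#' @export
entity_coverage <- function(graph, ms) {
  if (length(ms$markers) == 0) abort("marker set must be non-empty")
  detected <- purrr::imap_lgl(ms$markers, ~ marker_hit(graph, .y, .x))
  structure(
    list(
      pathway_id = ms$pathway_id, name = ms$name,
      external_ref = ms$external_ref,
      M_detected = sum(detected), M_total = length(detected),
      C_entity = round_half_up(sum(detected) / length(detected) * 100, 1),
      detected_markers = names(ms$markers)[detected],
      missing_markers = names(ms$markers)[!detected],
      R_found = NA_integer_, R_expected = NA_integer_, C_edge = NA_real_,
      found_edges = NULL, missing_edges = NULL
    ),
    class = "kg_coverage"
  )
}

expected_edge_found <- function(graph, ms, src, tgt, directed = TRUE) {
  src_nodes <- matches_keyword(graph$nodes$label,
                               unique(c(src, ms$markers[[src]])))
  tgt_nodes <- matches_keyword(graph$nodes$label,
                               unique(c(tgt, ms$markers[[tgt]])))
  src_lab <- graph$nodes$label[src_nodes]
  tgt_lab <- graph$nodes$label[tgt_nodes]
  hit <- any(graph$edges$source %in% src_lab & graph$edges$target %in% tgt_lab)
  if (!directed) {
    hit <- hit || any(graph$edges$source %in% tgt_lab &
                        graph$edges$target %in% src_lab)
  }
  hit
}

#' Edge coverage of a marker set
#'
#' An expected edge is found when any graph edge of any relation type
#' connects nodes matching its two markers, in the stated direction by
#' default (`directed = FALSE` relaxes this).
#'
#' @param graph A `kg_graph`.
#' @param ms A `kg_marker_set` with `expected_edges`.
#' @param directed Respect edge direction (default TRUE).
#' @return A `kg_coverage` with the edge fields filled in on top of the
#'   entity fields; when the marker set carries no expected edges, the edge
#'   part is NA ("not applicable").
#' @export
edge_coverage <- function(graph, ms, directed = TRUE) {
  out <- entity_coverage(graph, ms)
  ee <- ms$expected_edges
  if (is.null(ee) || nrow(ee) == 0) {
    return(out)
  }
  found <- purrr::map2_lgl(ee$source, ee$target,
                           ~ expected_edge_found(graph, ms, .x, .y, directed))
  out$R_found <- sum(found)
  out$R_expected <- nrow(ee)
  out$C_edge <- round_half_up(sum(found) / nrow(ee) * 100, 1)
  out$found_edges <- ee[found, , drop = FALSE]
  out$missing_edges <- ee[!found, , drop = FALSE]
  out
}

#' @export
print.kg_coverage <- function(x, ...) {
  cat("<kg_coverage>", x$name, "—",
      paste0(x$C_entity, "% (", x$M_detected, "/", x$M_total, ")"))
  if (!is.na(x$C_edge)) {
    cat(", edges", paste0(x$C_edge, "% (", x$R_found, "/", x$R_expected, ")"))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a coverage report
#'
#' @param x A `kg_coverage`.
#' @param ... Unused.
#' @return One-row tibble with the counts and percentage coverages.
#' @method tidy kg_coverage
#' @export
tidy.kg_coverage <- function(x, ...) {
  tibble(
    pathway_id = x$pathway_id, name = x$name, external_ref = x$external_ref,
    M_detected = x$M_detected, M_total = x$M_total, C_entity = x$C_entity,
    R_found = x$R_found, R_expected = x$R_expected, C_edge = x$C_edge
  )
}

#' Benchmark summary over several coverage reports
#'
#' @param reports Non-empty list of `kg_coverage` objects.
#' @return A `kg_benchmark` list: `table` (one row per pathway, coverage
#'   formatted as `"xx.x% (d/t)"`), and `mean_entity_coverage` — the
#'   unweighted mean of the per-pathway entity coverages, one decimal.
#' @export
benchmark_summary <- function(reports) {
  if (length(reports) == 0) abort("need at least one coverage report")
  tbl <- bind_rows(purrr::map(reports, tidy)) |>
    mutate(
      entity_coverage = paste0(.data$C_entity, "% (", .data$M_detected,
                               "/", .data$M_total, ")"),
      edge_coverage = ifelse(
        is.na(.data$C_edge), "",
        paste0(.data$C_edge, "% (", .data$R_found, "/", .data$R_expected, ")")
      )
    )
  structure(
    list(
      table = tbl,
      mean_entity_coverage = round_half_up(mean(tbl$C_entity), 1)
    ),
    class = "kg_benchmark"
  )
}

#' @export
print.kg_benchmark <- function(x, ...) {
  cat("<kg_benchmark> mean entity coverage:",
      paste0(x$mean_entity_coverage, "%\n"))
  print(select(x$table, "pathway_id", "external_ref", "entity_coverage",
               "edge_coverage"))
  invisible(x)
}

#' Write a benchmark report
#'
#' TSV table (pathway, external ref, formatted coverages) with a trailing
#' mean row, plus JSON carrying the full detected/missing lists.
#'
#' @param reports List of `kg_coverage`.
#' @param dir Output directory.
#' @param meta Optional named list merged into the JSON.
#' @return Invisibly, the `kg_benchmark` summary.
#' @export
write_benchmark_report <- function(reports, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bench <- benchmark_summary(reports)
  out_tbl <- bench$table |>
    select("pathway_id", "name", "external_ref", "entity_coverage",
           "edge_coverage") |>
    bind_rows(tibble(
      pathway_id = "mean", name = "unweighted mean", external_ref = "",
      entity_coverage = paste0(bench$mean_entity_coverage, "%"),
      edge_coverage = ""
    ))
  readr::write_tsv(out_tbl, file.path(dir, "benchmark.tsv"))
  detail <- purrr::map(reports, function(r) {
    list(
      pathway_id = r$pathway_id, external_ref = r$external_ref,
      M_detected = r$M_detected, M_total = r$M_total, C_entity = r$C_entity,
      detected_markers = r$detected_markers,
      missing_markers = r$missing_markers,
      R_found = r$R_found, R_expected = r$R_expected, C_edge = r$C_edge,
      found_edges = r$found_edges, missing_edges = r$missing_edges
    )
  })
  jsonlite::write_json(
    c(list(mean_entity_coverage = bench$mean_entity_coverage,
           pathways = detail), meta),
    file.path(dir, "benchmark.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(bench)
}
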