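# Mechanistic-pathway evidence: keyword-driven identification of
# Diet -> Microbiome -> Metabolite -> Outcome chains and their evidence
# metrics (unique supporting documents, relation instances).

KG_STAGE_ROLES <- c("diet", "microbiome", "metabolite", "outcome")

#' Define a mechanistic pathway
#'
#' A pathway is an ordered list of stages — each a role (diet, microbiome,
#' metabolite, outcome) with a non-empty keyword list — plus an optional
#' list of expected edges. Stages may be skipped when traversing (a chain
#' can run diet -> microbiome -> outcome), but never revisited out of order.
#'
#' @param pathway_id Short identifier.
#' @param name Human-readable pathway name.
#' @param polarity_claim `"beneficial"` or `"harmful"`.
#' @param stages Named list `role = character vector of keywords`, in stage
#'   order; at least 2 stages.
#' @param expected_edges Optional tibble (source_keyword, target_keyword,
#'   relation_type; `"*"` wildcard for any type).
#' @return A `kg_pathway` list.
#' @examples
#' fiber_axis <- pathway_definition(
#'   "fiber_scfa", "Fiber-SCFA-Inflammation", "beneficial",
#'   stages = list(
#'     diet = c("dietary fiber", "fiber"),
#'     microbiome = "Faecalibacterium",
#'     metabolite = "butyrate",
#'     outcome = c("inflammation", "intestinal barrier")
#'   )
#' )
#' @export
pathway_definition <- function(pathway_id, name = pathway_id,
                               polarity_claim = c("beneficial", "harmful"),
                               stages, expected_edges = NULL) {
  polarity_claim <- match.arg(polarity_claim)
  if (length(stages) < 2) abort("a pathway needs at least 2 stages")
  bad_role <- setdiff(names(stages), KG_STAGE_ROLES)
  if (length(bad_role) > 0) {
    abort(paste0("unknown stage roles: ", paste(bad_role, collapse = ", ")))
  }
  if (any(!purrr::map_lgl(stages, ~ length(.x) > 0 && all(nzchar(.x))))) {
    abort("every stage needs a non-empty keyword list")
  }
  structure(
    list(
      pathway_id = pathway_id, name = name,
      polarity_claim = polarity_claim,
      stages = purrr::map(stages, as.character),
      expected_edges = expected_edges
    ),
    class = "kg_pathway"
  )
}

#' Read pathway definitions from JSON
#'
#' The JSON file holds an array of objects with fields `pathway_id`, `name`,
#' `polarity_claim`, `stages` (object mapping role to keyword array), and
#' optionally `expected_edges`.
#'
#' @param path JSON file path.
#' @return List of `kg_pathway` objects.
#' @export
read_pathway_definitions <- function(path) {
  if (!file.exists(path)) abort(paste0("pathway file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  purrr::map(raw, function(p) {
    pathway_definition(
      pathway_id = p$pathway_id,
      name = p$name %||% p$pathway_id,
      polarity_claim = p$polarity_claim,
      stages = purrr::map(p$stages, unlist),
      expected_edges = if (!is.null(p$expected_edges)) {
        bind_rows(purrr::map(p$expected_edges, as_tibble))
      }
    )
  })
}

#' Match graph nodes against a keyword list
#'
#' A node matches when its normalized label equals a keyword
#' (case-insensitively) or contains it as a whole word
#' (see [matches_keyword()]).
#'
#' @param graph A `kg_graph`.
#' @param keywords Non-empty character vector.
#' @return Character vector of matched node labels.
#' @export
match_entities <- function(graph, keywords) {
  if (length(keywords) == 0) abort("keywords must be non-empty")
  graph$nodes$label[matches_keyword(graph$nodes$label, keywords)]
}

# Stage indices each node can occupy: list(label -> integer vector)
stage_matches <- function(graph, definition) {
  purrr::imap(definition$stages, function(kws, role) {
    match_entities(graph, kws)
  })
}

node_stage_sets <- function(graph, definition) {
  per_stage <- stage_matches(graph, definition)
  labels <- unique(unlist(per_stage))
  setNames(
    purrr::map(labels, function(l) {
      which(purrr::map_lgl(per_stage, ~ l %in% .x))
    }),
    labels
  )
}

#' Evidence metrics for a pathway definition
#'
#' An edge supports the pathway when both endpoints match some stage's
#' keywords and its direction is consistent with stage order: the source
#' must be assignable to a stage no later than the target's
#' (same-stage edges allowed). Metrics: `docs` is the number of unique
#' supporting documents pooled over matched edges; `rels` is the number of
#' relation instances they aggregate (not unique edges).
#'
#' @param graph A `kg_graph` whose edges carry `supporting_docs`.
#' @param definition A `kg_pathway`.
#' @return A `kg_evidence` list: pathway_id, name, polarity_claim, docs,
#'   rels, matched_nodes (tibble label/stage roles), matched_edges (edge
#'   tibble).
#' @export
pathway_evidence <- function(graph, definition) {
  stages <- node_stage_sets(graph, definition)
  e <- graph$edges
  if (nrow(e) == 0 || length(stages) == 0) {
    return(empty_evidence(definition))
  }
  src_ok <- purrr::map(e$source, ~ stages[[.x]] %||% integer())
  tgt_ok <- purrr::map(e$target, ~ stages[[.x]] %||% integer())
  keep <- purrr::map2_lgl(src_ok, tgt_ok, function(s, t) {
    length(s) > 0 && length(t) > 0 && min(s) <= max(t)
  })
  matched <- e[keep, , drop = FALSE]
  matched_nodes <- tibble(
    label = names(stages),
    stages = purrr::map_chr(stages, ~ paste(names(definition$stages)[.x],
                                            collapse = ","))
  )
  structure(
    list(
      pathway_id = definition$pathway_id,
      name = definition$name,
      polarity_claim = definition$polarity_claim,
      docs = n_distinct(unlist(matched$supporting_docs)),
      rels = sum(matched$instance_count),
      matched_nodes = matched_nodes,
      matched_edges = matched
    ),
    class = "kg_evidence"
  )
}

empty_evidence <- function(definition) {
  structure(
    list(
      pathway_id = definition$pathway_id, name = definition$name,
      polarity_claim = definition$polarity_claim,
      docs = 0L, rels = 0L,
      matched_nodes = tibble(label = character(), stages = character()),
      matched_edges = empty_edges() |> mutate(weight = numeric())
    ),
    class = "kg_evidence"
  )
}

#' @export
print.kg_evidence <- function(x, ...) {
  cat("<kg_evidence>", x$name, "—", x$docs, "docs,", x$rels, "rels\n")
  invisible(x)
}

#' Tidy evidence metrics for a set of pathways
#'
#' @param graph A `kg_graph`.
#' @param definitions List of `kg_pathway` objects.
#' @return Tibble (pathway_id, name, polarity, docs, rels, chain) — one row
#'   per pathway, chain being the rendering of its best extracted chain
#'   (empty when none).
#' @export
pathway_evidence_table <- function(graph, definitions) {
  rows <- purrr::map(definitions, function(d) {
    ev <- pathway_evidence(graph, d)
    chains <- extract_chains(graph, d)
    tibble(
      pathway_id = ev$pathway_id,
      name = ev$name,
      polarity = ev$polarity_claim,
      docs = ev$docs,
      rels = ev$rels,
      chain = if (length(chains) > 0) render_chain(chains[[1]]) else ""
    )
  })
  bind_rows(rows) %0% tibble(
    pathway_id = character(), name = character(), polarity = character(),
    docs = integer(), rels = integer(), chain = character()
  )
}

#' Enumerate stage-ordered mechanistic chains
#'
#' Performs a depth-first enumeration of simple directed paths that start at
#' a diet-stage (first-stage) match, end at an outcome-stage (last-stage)
#' match, and visit stages in non-decreasing order; stages may be skipped.
#' Chains carry their per-edge weights and supporting documents. Chains are
#' returned longest first, then by descending total weight.
#'
#' @param graph A `kg_graph`.
#' @param definition A `kg_pathway`.
#' @param max_path_len Maximum number of nodes per chain (default 6;
#'   must be >= 2).
#' @return List of chains; each chain is a list with `nodes` (labels),
#'   `stages` (stage roles), and `edges` (edge tibble rows in path order).
#' @export
extract_chains <- function(graph, definition, max_path_len = 6) {
  if (max_path_len < 2) abort("max_path_len must be >= 2")
  stages <- node_stage_sets(graph, definition)
  n_stage <- length(definition$stages)
  if (length(stages) == 0 || nrow(graph$edges) == 0) return(list())
  adj <- split(seq_len(nrow(graph$edges)), graph$edges$source)
  chains <- list()
  walk <- function(node, stage, visited, edge_idx) {
    if (stage == n_stage) {
      chains[[length(chains) + 1]] <<- list(nodes = visited, edge_idx = edge_idx)
      # an outcome node may still lead deeper within the outcome stage
    }
    if (length(visited) >= max_path_len) return(invisible())
    for (i in adj[[node]] %||% integer()) {
      nxt <- graph$edges$target[i]
      if (nxt %in% visited) next
      nxt_stages <- stages[[nxt]] %||% integer()
      ok <- nxt_stages[nxt_stages >= stage]
      for (s in ok) {
        walk(nxt, s, c(visited, nxt), c(edge_idx, i))
      }
    }
  }
  for (start in names(stages)) {
    if (1 %in% stages[[start]]) walk(start, 1L, start, integer())
  }
  # drop single-node "chains" (a node matching both first and last stage)
  chains <- purrr::keep(chains, ~ length(.x$nodes) >= 2)
  # deduplicate node sequences reached via different stage assignments
  keys <- purrr::map_chr(chains, ~ paste(.x$nodes, collapse = "\r"))
  chains <- chains[!duplicated(keys)]
  chains <- purrr::map(chains, function(ch) {
    e <- graph$edges[ch$edge_idx, , drop = FALSE]
    list(
      nodes = ch$nodes,
      stages = chain_stage_roles(ch$nodes, stages, definition),
      edges = e
    )
  })
  ord <- order(
    -purrr::map_int(chains, ~ length(.x$nodes)),
    -purrr::map_dbl(chains, ~ sum(.x$edges$weight)),
    purrr::map_chr(chains, ~ paste(.x$nodes, collapse = " "))
  )
  chains[ord]
}

chain_stage_roles <- function(nodes, stages, definition) {
  roles <- names(definition$stages)
  cur <- 1L
  out <- character(length(nodes))
  for (i in seq_along(nodes)) {
    s <- stages[[nodes[i]]]
    s <- s[s >= cur]
    cur <- min(s)
    out[i] <- roles[cur]
  }
  out
}

#' Render a chain with polarity arrows
#'
#' Beneficial-class edges (benefits, increases and any edge resolved
#' beneficial) decorate the target with an up arrow; reducing/inhibitory
#' edges with a down arrow; neutral edges with none.
#'
#' @param chain One chain from [extract_chains()].
#' @return A single string such as
#'   `"fiber -> Faecalibacterium prausnitzii ^ -> butyrate ^"`.
#' @export
render_chain <- function(chain) {
  out <- chain$nodes[1]
  if (nrow(chain$edges) > 0) {
    for (i in seq_len(nrow(chain$edges))) {
      mark <- switch(chain$edges$polarity[i],
                     beneficial = " ↑", harmful = " ↓", "")
      out <- paste0(out, " → ", chain$nodes[i + 1], mark)
    }
  }
  out
}

#' Write pathway-evidence reports
#'
#' A table TSV (pathway, polarity, docs, rels, chain rendering) plus a JSON
#' file with full matched nodes/edges per pathway. The JSON metadata notes
#' that `rels` counts relation instances, not unique edges.
#'
#' @param graph A `kg_graph`.
#' @param definitions List of `kg_pathway`.
#' @param dir Output directory.
#' @param meta Optional named list merged into the JSON.
#' @return Invisibly, `dir`.
#' @export
write_pathway_report <- function(graph, definitions, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- pathway_evidence_table(graph, definitions)
  readr::write_tsv(tbl, file.path(dir, "pathways.tsv"))
  detail <- purrr::map(definitions, function(d) {
    ev <- pathway_evidence(graph, d)
    list(
      pathway_id = ev$pathway_id, name = ev$name,
      polarity_claim = ev$polarity_claim,
      docs = ev$docs, rels = ev$rels,
      matched_nodes = ev$matched_nodes,
      matched_edges = ev$matched_edges |>
        mutate(supporting_docs = purrr::map_chr(.data$supporting_docs,
                                                paste, collapse = ";"))
    )
  })
  jsonlite::write_json(
    c(list(rels_semantics = "relation instances (not unique edges)",
           pathways = detail), meta),
    file.path(dir, "pathways.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
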