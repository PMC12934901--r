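# Pipeline orchestration: a run configuration shared by the build, topology,
# pathway, benchmark and simulate stages, each writing reproducible reports
# stamped with the configuration hash and package version.

#' Assemble a run configuration
#'
#' Either pass the fields directly or point `file` at a YAML document with
#' the same structure (`paths:` corpus/synonyms/schema/pathways/markers/out,
#' `options:` strict/hub_k/normalization/multipliers, `seed:`). Explicit
#' arguments override the file.
#'
#' @param file Optional YAML configuration path.
#' @param corpus Directory of .ann files.
#' @param synonyms Optional synonym-table TSV path.
#' @param schema Optional schema YAML path.
#' @param pathways Optional pathway-definitions JSON path.
#' @param markers Optional marker-sets JSON path.
#' @param out Output directory (default `"kg_out"`).
#' @param strict Strict parsing (default FALSE).
#' @param hub_k Hubs to report (default 10).
#' @param normalization Connectivity normalization, `"max"` or `"row"`.
#' @param multipliers Named list/vector of polarity multipliers.
#' @param seed Seed for the simulate stage (default 42).
#' @return A `kg_config` list.
#' @export
kg_config <- function(file = NULL, corpus = NULL, synonyms = NULL,
                      schema = NULL, pathways = NULL, markers = NULL,
                      out = NULL, strict = NULL, hub_k = NULL,
                      normalization = NULL, multipliers = NULL, seed = NULL) {
  base <- list(paths = list(), options = list(), seed = 42L)
  if (!is.null(file)) {
    if (!file.exists(file)) abort(paste0("config file not found: ", file))
    raw <- yaml::read_yaml(file)
    base$paths <- raw$paths %||% list()
    base$options <- raw$options %||% list()
    base$seed <- raw$seed %||% 42L
  }
  override <- function(cur, val) val %||% cur
  base$paths$corpus <- override(base$paths$corpus, corpus)
  base$paths$synonyms <- override(base$paths$synonyms, synonyms)
  base$paths$schema <- override(base$paths$schema, schema)
  base$paths$pathways <- override(base$paths$pathways, pathways)
  base$paths$markers <- override(base$paths$markers, markers)
  base$paths$out <- override(base$paths$out %||% "kg_out", out)
  base$options$strict <- override(base$options$strict %||% FALSE, strict)
  base$options$hub_k <- override(base$options$hub_k %||% 10L, hub_k)
  base$options$normalization <-
    override(base$options$normalization %||% "max", normalization)
  base$options$multipliers <- override(base$options$multipliers, multipliers)
  base$seed <- as.integer(override(base$seed, seed))
  structure(base, class = "kg_config")
}

config_meta <- function(config) {
  list(config_hash = config_hash(unclass(config)), package_version = pkg_version())
}

load_config_schema <- function(config) {
  if (!is.null(config$paths$schema)) read_schema(config$paths$schema)
  else kg_schema()
}

load_config_multipliers <- function(config, schema) {
  if (is.null(config$options$multipliers)) schema$multipliers
  else do.call(polarity_weights, as.list(config$options$multipliers))
}

#' Build stage: corpus -> graph artifacts
#'
#' Loads the corpus, synonym table and schema named in the configuration,
#' builds the knowledge graph, and writes `nodes.tsv`, `edges.tsv`,
#' `graph.graphml` and `build_log.json` under the output directory.
#'
#' @param config A `kg_config` with `paths$corpus` set.
#' @return Invisibly, the built `kg_graph`.
#' @export
cmd_build <- function(config) {
  if (is.null(config$paths$corpus)) abort("config has no corpus path")
  schema <- load_config_schema(config)
  pw <- load_config_multipliers(config, schema)
  syn <- if (is.null(config$paths$synonyms)) synonym_map() else
    load_synonym_table(config$paths$synonyms)
  corpus <- load_corpus(config$paths$corpus, schema = schema,
                        strict = isTRUE(config$options$strict))
  graph <- build_graph(corpus, syn, schema, pw)
  out <- config$paths$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_graph_tables(graph, out)
  write_graphml(graph, file.path(out, "graph.graphml"))
  jsonlite::write_json(
    c(graph$log, config_meta(config),
      list(parse_failures = nrow(attr(corpus, "failures")))),
    file.path(out, "build_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(graph)
}

#' Topology stage: graph artifacts -> topology report
#'
#' @param config A `kg_config`; expects graph artifacts under `paths$out`
#'   (run [cmd_build()] first).
#' @return Invisibly, the `kg_topology_report`.
#' @export
cmd_topology <- function(config) {
  graph <- read_graph_tables(config$paths$out)
  report <- topology_report(
    graph, k = config$options$hub_k,
    normalization = config$options$normalization
  )
  write_topology_report(report, file.path(config$paths$out, "topology"),
                        meta = config_meta(config))
  invisible(report)
}

#' Pathway stage: graph + definitions -> evidence reports
#'
#' With no definitions configured, writes an empty table and succeeds.
#'
#' @param config A `kg_config`.
#' @return Invisibly, the pathway evidence tibble.
#' @export
cmd_pathways <- function(config) {
  graph <- read_graph_tables(config$paths$out)
  defs <- if (is.null(config$paths$pathways)) list() else
    read_pathway_definitions(config$paths$pathways)
  dir <- file.path(config$paths$out, "pathways")
  write_pathway_report(graph, defs, dir, meta = config_meta(config))
  invisible(pathway_evidence_table(graph, defs))
}

#' Benchmark stage: graph + marker sets -> coverage reports
#'
#' @param config A `kg_config` with `paths$markers` set.
#' @return Invisibly, the `kg_benchmark` summary.
#' @export
cmd_benchmark <- function(config) {
  graph <- read_graph_tables(config$paths$out)
  if (is.null(config$paths$markers)) abort("config has no marker-set path")
  sets <- read_marker_sets(config$paths$markers)
  reports <- purrr::map(sets, ~ edge_coverage(graph, .x))
  bench <- write_benchmark_report(reports,
                                  file.path(config$paths$out, "benchmark"),
                                  meta = config_meta(config))
  invisible(bench)
}

#' Simulate stage: write a synthetic corpus with its manifest
#'
#' Generates the default synthetic corpus (or one from a spec produced by
#' [synthetic_spec()]) under `paths$out/synthetic`, seeded from the
#' configuration.
#'
#' @param config A `kg_config`.
#' @param spec Optional `kg_synthetic_spec`; defaults to
#'   [default_synthetic_spec()] at the configuration's seed.
#' @return Invisibly, the generator result (corpus, manifest, paths, ...).
#' @export
cmd_simulate <- function(config, spec = NULL) {
  spec <- spec %||% default_synthetic_spec(seed = config$seed)
  res <- generate_corpus(spec, dir = file.path(config$paths$out, "synthetic"))
  invisible(res)
}
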