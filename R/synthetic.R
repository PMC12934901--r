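# Synthetic annotated corpora with a ground-truth manifest.
#
# The generator emulates the statistical structure the analysis assumes:
# per-triple evidence frequencies across unique abstracts (~1-9), a
# three-class polarity mix for background edges (62.6/23.1/14.3 by default),
# lexical variant fragmentation of entity labels, isolated (relation-free)
# mentions, and planted multi-step diet -> microbiome -> metabolite ->
# outcome chains distributed across documents. Every quantity the pipeline
# should recover is recorded in the manifest from the generator's own
# bookkeeping (exact label equality, closed-form weights), independently of
# the pipeline code paths under test.

#' Specification for a synthetic annotated corpus
#'
#' @param n_documents Number of abstracts (each becomes one .ann file).
#' @param planted_edges Optional tibble of triples to plant: columns
#'   `source`, `source_category`, `target`, `target_category`,
#'   `relation_type`, `polarity` (NA uses the type default), `frequency`
#'   (unique supporting documents, 1 <= F <= n_documents), and optionally
#'   `duplicates` (extra within-document instances, default 0).
#' @param planted_pathways List of planted chains; each element is a list
#'   with `pathway_id`, `polarity_claim`, `nodes` (tibble label, category,
#'   stage in diet/microbiome/metabolite/outcome) and `edges` (same columns
#'   as `planted_edges`).
#' @param polarity_mix Named proportions (beneficial/harmful/neutral) for
#'   background distractor edges; must sum to 1.
#' @param n_distractor_edges Number of background triples.
#' @param n_distractor_labels Label-pool size per distractor category.
#' @param distractor_categories Categories used for distractor nodes.
#' @param max_distractor_frequency Upper truncation of the distractor
#'   frequency distribution (geometric-like, mostly singletons).
#' @param variant_table Optional tibble (`normalized`, `variant`,
#'   `n_occurrences`) planting lexical variants of planted labels.
#' @param n_isolated_mentions Relation-free mentions to scatter (pruned
#'   during graph construction).
#' @param marker_sets List of `kg_marker_set` objects to benchmark against
#'   (ground-truth coverage is recorded in the manifest).
#' @param seed Integer seed; all randomness flows through it.
#' @return A validated `kg_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_documents = 200,
                           planted_edges = NULL,
                           planted_pathways = list(),
                           polarity_mix = c(neutral = 0.626,
                                            beneficial = 0.231,
                                            harmful = 0.143),
                           n_distractor_edges = 1000,
                           n_distractor_labels = 120,
                           distractor_categories = c("nutrition", "microbiome",
                                                     "metabolite",
                                                     "clinical_outcome",
                                                     "disease"),
                           max_distractor_frequency = 9,
                           variant_table = NULL,
                           n_isolated_mentions = 40,
                           marker_sets = list(),
                           seed = 42) {
  if (abs(sum(polarity_mix) - 1) > 1e-9) {
    abort("polarity_mix proportions must sum to 1")
  }
  if (!setequal(names(polarity_mix), KG_POLARITIES)) {
    abort("polarity_mix needs names beneficial/harmful/neutral")
  }
  spec <- structure(
    list(
      n_documents = as.integer(n_documents),
      planted_edges = planted_edges,
      planted_pathways = planted_pathways,
      polarity_mix = polarity_mix[KG_POLARITIES],
      n_distractor_edges = as.integer(n_distractor_edges),
      n_distractor_labels = as.integer(n_distractor_labels),
      distractor_categories = distractor_categories,
      max_distractor_frequency = as.integer(max_distractor_frequency),
      variant_table = variant_table,
      n_isolated_mentions = as.integer(n_isolated_mentions),
      marker_sets = marker_sets,
      seed = as.integer(seed)
    ),
    class = "kg_synthetic_spec"
  )
  planted <- collect_planted_edges(spec)
  if (nrow(planted) > 0) {
    if (any(planted$frequency < 1) ||
        any(planted$frequency > spec$n_documents)) {
      abort("planted frequency must satisfy 1 <= F <= n_documents")
    }
    key <- paste(planted$source, planted$target, planted$relation_type)
    if (anyDuplicated(key)) abort("duplicate planted triples")
  }
  spec
}

collect_planted_edges <- function(spec) {
  canon <- function(e) {
    e <- as_tibble(e)
    if (!"polarity" %in% names(e)) e$polarity <- NA_character_
    if (!"duplicates" %in% names(e)) e$duplicates <- 0L
    e |> mutate(frequency = as.integer(.data$frequency),
                duplicates = as.integer(.data$duplicates))
  }
  parts <- c(
    if (!is.null(spec$planted_edges)) list(canon(spec$planted_edges)),
    purrr::map(spec$planted_pathways, ~ canon(.x$edges))
  )
  if (length(parts) == 0) {
    return(tibble(
      source = character(), source_category = character(),
      target = character(), target_category = character(),
      relation_type = character(), polarity = character(),
      frequency = integer(), duplicates = integer()
    ))
  }
  bind_rows(parts)
}

doc_ids_for <- function(n) sprintf("4%07d", seq_len(n))

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the spec and its seed: each planted triple appears in
#' exactly `frequency` distinct documents (sampled without replacement, plus
#' optional within-document duplicate instances so `instance_count` can
#' exceed `frequency`), lexical variants replace canonical surfaces per the
#' variant table, and isolated mentions are attached to random documents.
#' Rerunning with the same spec yields byte-identical files.
#'
#' @param spec A `kg_synthetic_spec`.
#' @param dir Optional output directory; when given, writes `corpus/*.ann`
#'   (one per document, including annotation-free documents), the synonym
#'   TSV, pathway and marker-set JSON, and `manifest.json`.
#' @return List with `corpus` (a `kg_corpus`), `synonym_map`,
#'   `pathways` (list of `kg_pathway`), `marker_sets`, `schema`,
#'   `manifest` (ground truth), and `paths` (when `dir` was given).
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "kg_synthetic_spec"))
  schema <- kg_schema()
  docs <- doc_ids_for(spec$n_documents)

  res <- with_seed(spec$seed, {
    planted <- collect_planted_edges(spec)
    node_cat <- c(
      setNames(planted$source_category, planted$source),
      setNames(planted$target_category, planted$target)
    )
    distract <- generate_distractors(spec, schema, forbidden = names(node_cat))
    node_cat <- c(node_cat, distract$node_cat)
    node_cat <- node_cat[!duplicated(names(node_cat))]

    edges <- bind_rows(
      planted |> mutate(planted = TRUE),
      distract$edges |> mutate(planted = FALSE)
    )
    if (nrow(edges) > 0) {
      edges$polarity <- ifelse(
        is.na(edges$polarity),
        default_polarity(edges$relation_type, schema),
        edges$polarity
      )
      edges$docs <- purrr::map(edges$frequency, function(f) {
        sort(sample(docs, f, replace = FALSE))
      })
    } else {
      edges$docs <- list()
    }

    # one relation instance per (edge, doc); duplicates repeat the first doc
    inst <- if (nrow(edges) == 0) {
      tibble(edge = integer(), doc_id = character())
    } else {
      purrr::map_dfr(seq_len(nrow(edges)), function(i) {
        d <- edges$docs[[i]]
        tibble(edge = i,
               doc_id = c(d, rep(d[1], edges$duplicates[i])))
      }) |> arrange(.data$doc_id, .data$edge)
    }

    iso <- if (spec$n_isolated_mentions > 0) {
      tibble(
        label = sprintf("isolated_%03d", seq_len(spec$n_isolated_mentions)),
        category = sample(spec$distractor_categories,
                          spec$n_isolated_mentions, replace = TRUE),
        doc_id = sample(docs, spec$n_isolated_mentions, replace = TRUE)
      )
    } else {
      tibble(label = character(), category = character(), doc_id = character())
    }
    list(edges = edges, inst = inst, iso = iso, node_cat = node_cat)
  })
  edges <- res$edges
  inst <- res$inst
  iso <- res$iso
  node_cat <- res$node_cat

  corpus <- assemble_corpus(edges, inst, iso, node_cat, docs)
  corpus <- plant_variants(corpus, spec$variant_table)
  syn_map <- synonym_map(
    if (is.null(spec$variant_table)) {
      tibble(normalized = character(), variant = character())
    } else {
      spec$variant_table |> select("normalized", "variant")
    }
  )
  pathways <- purrr::map(spec$planted_pathways, planted_pathway_definition)
  manifest <- build_manifest(spec, edges, inst, iso, corpus, pathways, schema)

  out <- list(
    corpus = corpus, synonym_map = syn_map, pathways = pathways,
    marker_sets = spec$marker_sets, schema = schema, manifest = manifest
  )
  if (!is.null(dir)) {
    out$paths <- write_synthetic(out, spec, dir, docs)
  }
  out
}

generate_distractors <- function(spec, schema, forbidden) {
  n <- spec$n_distractor_edges
  if (n == 0) {
    return(list(
      edges = tibble(
        source = character(), source_category = character(),
        target = character(), target_category = character(),
        relation_type = character(), polarity = character(),
        frequency = integer(), duplicates = integer()
      ),
      node_cat = character()
    ))
  }
  pool <- purrr::map_dfr(spec$distractor_categories, function(cat) {
    tibble(
      label = sprintf("bg_%s_%03d", cat, seq_len(spec$n_distractor_labels)),
      category = cat
    )
  })
  by_class <- split(schema$relation_types, schema$type_to_polarity)
  fmax <- min(spec$max_distractor_frequency, spec$n_documents)
  fprob <- 0.35^(seq_len(fmax) - 1)
  seen <- character()
  rows <- list()
  attempts <- 0
  while (length(rows) < n && attempts < n * 20) {
    attempts <- attempts + 1
    ij <- sample(nrow(pool), 2, replace = FALSE)
    cls <- sample(KG_POLARITIES, 1, prob = spec$polarity_mix[KG_POLARITIES])
    type <- sample(by_class[[cls]], 1)
    key <- paste(pool$label[ij[1]], pool$label[ij[2]], type)
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1]] <- tibble(
      source = pool$label[ij[1]], source_category = pool$category[ij[1]],
      target = pool$label[ij[2]], target_category = pool$category[ij[2]],
      relation_type = type, polarity = cls,
      frequency = sample(fmax, 1, prob = fprob), duplicates = 0L
    )
  }
  edges <- bind_rows(rows)
  list(
    edges = edges,
    node_cat = c(setNames(pool$category, pool$label))
  )
}

assemble_corpus <- function(edges, inst, iso, node_cat, docs) {
  # every relation instance contributes a fresh source/target mention pair;
  # isolated mentions follow the relation mentions within each document
  if (nrow(inst) > 0) {
    src <- edges$source[inst$edge]
    tgt <- edges$target[inst$edge]
    inst_m <- tibble(
      doc_id = rep(inst$doc_id, each = 2),
      surface = as.vector(rbind(src, tgt)),
      block = 1L
    )
  } else {
    inst_m <- tibble(doc_id = character(), surface = character(),
                     block = integer())
  }
  iso_m <- tibble(doc_id = iso$doc_id, surface = iso$label, block = 2L)
  m <- bind_rows(inst_m, iso_m) |>
    mutate(.ord = row_number()) |>
    arrange(.data$doc_id, .data$block, .data$.ord) |>
    group_by(.data$doc_id) |>
    mutate(
      mention_id = paste0("T", row_number()),
      span_end = cumsum(nchar(.data$surface) + 1L) - 1L,
      span_start = .data$span_end - nchar(.data$surface)
    ) |>
    ungroup() |>
    mutate(category = unname(
      c(node_cat, setNames(iso$category, iso$label))[.data$surface]
    )) |>
    select("doc_id", "mention_id", "category", "surface",
           "span_start", "span_end")
  r <- if (nrow(inst) == 0) empty_relations() else {
    inst |>
      group_by(.data$doc_id) |>
      mutate(k = row_number()) |>
      ungroup() |>
      mutate(
        relation_id = paste0("R", .data$k),
        relation_type = edges$relation_type[.data$edge],
        polarity = edges$polarity[.data$edge],
        source_mention = paste0("T", 2L * .data$k - 1L),
        target_mention = paste0("T", 2L * .data$k)
      ) |>
      select("doc_id", "relation_id", "relation_type", "polarity",
             "source_mention", "target_mention")
  }
  new_corpus(
    if (nrow(m) == 0) empty_mentions() else m,
    r
  )
}

plant_variants <- function(corpus, variant_table) {
  if (is.null(variant_table) || nrow(variant_table) == 0) return(corpus)
  m <- corpus$mentions
  for (i in seq_len(nrow(variant_table))) {
    v <- variant_table[i, ]
    idx <- which(m$surface == v$normalized)
    take <- head(idx, v$n_occurrences)
    m$surface[take] <- v$variant
  }
  new_corpus(m, corpus$relations)
}

planted_pathway_definition <- function(p) {
  nodes <- as_tibble(p$nodes)
  stages <- purrr::map(
    split(nodes$label, factor(nodes$stage, levels = KG_STAGE_ROLES)),
    identity
  )
  stages <- stages[purrr::map_int(stages, length) > 0]
  pathway_definition(
    pathway_id = p$pathway_id,
    name = p$name %||% p$pathway_id,
    polarity_claim = p$polarity_claim,
    stages = stages
  )
}

variant_replacements <- function(corpus_before, variant_table) {
  # how many mentions actually carry a table variant surface
  if (is.null(variant_table) || nrow(variant_table) == 0) {
    return(list(mentions_unified = 0L, normalized_forms = 0L))
  }
  hits <- purrr::map_int(seq_len(nrow(variant_table)), function(i) {
    sum(corpus_before$mentions$surface == variant_table$variant[i])
  })
  list(
    mentions_unified = sum(hits),
    normalized_forms = n_distinct(variant_table$normalized[hits > 0])
  )
}

build_manifest <- function(spec, edges, inst, iso, corpus, pathways, schema) {
  pw <- schema$multipliers
  edge_tbl <- if (nrow(edges) == 0) {
    tibble(
      source = character(), target = character(), relation_type = character(),
      polarity = character(), frequency = integer(),
      instance_count = integer(), weight = numeric(), planted = logical(),
      supporting_docs = list()
    )
  } else {
    tibble(
      source = edges$source, target = edges$target,
      relation_type = edges$relation_type, polarity = edges$polarity,
      frequency = edges$frequency,
      instance_count = edges$frequency + edges$duplicates,
      weight = log(edges$frequency + 1) * unname(pw[edges$polarity]),
      planted = edges$planted,
      supporting_docs = edges$docs
    ) |> arrange(.data$source, .data$target, .data$relation_type)
  }
  node_labels <- unique(c(edge_tbl$source, edge_tbl$target))
  pathway_truth <- purrr::map_dfr(seq_along(spec$planted_pathways), function(k) {
    p <- spec$planted_pathways[[k]]
    nodes <- as_tibble(p$nodes)
    stage_of <- setNames(match(nodes$stage, KG_STAGE_ROLES), nodes$label)
    keep <- edge_tbl$source %in% nodes$label & edge_tbl$target %in% nodes$label
    keep <- keep & stage_of[edge_tbl$source] <= stage_of[edge_tbl$target]
    keep[is.na(keep)] <- FALSE
    matched <- edge_tbl[keep, , drop = FALSE]
    tibble(
      pathway_id = p$pathway_id,
      docs = n_distinct(unlist(matched$supporting_docs)),
      rels = sum(matched$instance_count)
    )
  })
  coverage_truth <- purrr::map_dfr(spec$marker_sets, function(ms) {
    det <- purrr::imap_lgl(ms$markers, function(syn, mk) {
      any(unique(c(mk, syn)) %in% node_labels)
    })
    ee <- ms$expected_edges
    if (is.null(ee) || nrow(ee) == 0) {
      rf <- NA_integer_; re <- NA_integer_; ce <- NA_real_
    } else {
      found <- purrr::map2_lgl(ee$source, ee$target, function(s, t) {
        s_lab <- intersect(unique(c(s, ms$markers[[s]])), node_labels)
        t_lab <- intersect(unique(c(t, ms$markers[[t]])), node_labels)
        any(edge_tbl$source %in% s_lab & edge_tbl$target %in% t_lab)
      })
      rf <- sum(found); re <- nrow(ee)
      ce <- round_half_up(rf / re * 100, 1)
    }
    tibble(
      pathway_id = ms$pathway_id,
      M_detected = sum(det), M_total = length(det),
      C_entity = round_half_up(sum(det) / length(det) * 100, 1),
      R_found = rf, R_expected = re, C_edge = ce
    )
  })
  cons <- variant_replacements(corpus, spec$variant_table)
  list(
    seed = spec$seed,
    totals = list(
      documents = spec$n_documents,
      mentions = nrow(corpus$mentions),
      relation_instances = nrow(corpus$relations)
    ),
    edges = edge_tbl,
    nodes_after_pruning = length(node_labels),
    entities_before_pruning = length(node_labels) +
      n_distinct(iso$label),
    unique_edges = nrow(edge_tbl),
    polarity_mix_realized = as.list(prop.table(table(
      factor(edge_tbl$polarity[!edge_tbl$planted], levels = KG_POLARITIES)
    ))),
    consolidation = cons,
    pathways = pathway_truth,
    coverage = coverage_truth
  )
}

write_synthetic <- function(out, spec, dir, docs) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus_dir <- file.path(dir, "corpus")
  dir.create(corpus_dir, showWarnings = FALSE)
  write_standoff(out$corpus, corpus_dir)
  # documents without annotations still get (empty) files
  present <- sub("\\.ann$", "", list.files(corpus_dir, pattern = "\\.ann$"))
  for (d in setdiff(docs, present)) {
    writeLines(character(), file.path(corpus_dir, paste0(d, ".ann")),
               useBytes = TRUE)
  }
  syn_path <- file.path(dir, "synonyms.tsv")
  readr::write_tsv(
    out$synonym_map$entries |>
      select(normalized_label = "normalized", variant_label = "variant"),
    syn_path
  )
  pathway_path <- file.path(dir, "pathways.json")
  jsonlite::write_json(
    purrr::map(out$pathways, function(p) {
      list(pathway_id = p$pathway_id, name = p$name,
           polarity_claim = p$polarity_claim, stages = p$stages)
    }),
    pathway_path, auto_unbox = TRUE, pretty = TRUE
  )
  marker_path <- file.path(dir, "markers.json")
  jsonlite::write_json(
    purrr::map(out$marker_sets, function(ms) {
      list(pathway_id = ms$pathway_id, name = ms$name,
           external_ref = ms$external_ref, markers = ms$markers,
           expected_edges = ms$expected_edges)
    }),
    marker_path, auto_unbox = TRUE, pretty = TRUE
  )
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- out$manifest
  manifest$edges <- manifest$edges |>
    mutate(supporting_docs = purrr::map_chr(.data$supporting_docs,
                                            paste, collapse = ";"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  list(dir = dir, corpus = corpus_dir, synonyms = syn_path,
       pathways = pathway_path, markers = marker_path,
       manifest = manifest_path)
}

#' Default synthetic-corpus specification
#'
#' Encodes the study conditions the generator emulates: 200 abstracts; two
#' planted mechanistic chains (a beneficial fiber -> Faecalibacterium ->
#' butyrate -> inflammation axis and a harmful high-fat diet -> dysbiosis ->
#' LPS -> insulin-resistance cascade) with per-edge evidence frequencies
#' spanning the 3-9 range; 1000 background edges drawn with the
#' 62.6/23.1/14.3 neutral/beneficial/harmful polarity mix and mostly
#' singleton frequencies; lexical variants of three planted labels; 40
#' isolated mentions; and two synthetic marker sets with expected-edge
#' lists for coverage benchmarking.
#'
#' @param seed Integer seed.
#' @return A `kg_synthetic_spec`.
#' @export
default_synthetic_spec <- function(seed = 42) {
  fiber <- list(
    pathway_id = "fiber_scfa_inflammation",
    name = "Fiber-SCFA-Inflammation",
    polarity_claim = "beneficial",
    nodes = tibble(
      label = c("dietary fiber", "Faecalibacterium prausnitzii",
                "butyrate", "inflammation"),
      category = c("nutrition", "microbiome", "metabolite",
                   "clinical_outcome"),
      stage = c("diet", "microbiome", "metabolite", "outcome")
    ),
    edges = tibble(
      source = c("dietary fiber", "Faecalibacterium prausnitzii", "butyrate"),
      source_category = c("nutrition", "microbiome", "metabolite"),
      target = c("Faecalibacterium prausnitzii", "butyrate", "inflammation"),
      target_category = c("microbiome", "metabolite", "clinical_outcome"),
      relation_type = c("increases", "increases", "reduces"),
      polarity = c(NA, NA, "beneficial"),
      frequency = c(9L, 6L, 5L),
      duplicates = c(2L, 0L, 1L)
    )
  )
  hfd <- list(
    pathway_id = "hfd_lps_insulin_resistance",
    name = "High-Fat-LPS-Metabolic Dysfunction",
    polarity_claim = "harmful",
    nodes = tibble(
      label = c("high-fat diet", "dysbiosis", "LPS", "insulin resistance"),
      category = c("nutrition", "microbiome", "metabolite",
                   "clinical_outcome"),
      stage = c("diet", "microbiome", "metabolite", "outcome")
    ),
    edges = tibble(
      source = c("high-fat diet", "dysbiosis", "LPS"),
      source_category = c("nutrition", "microbiome", "metabolite"),
      target = c("dysbiosis", "LPS", "insulin resistance"),
      target_category = c("microbiome", "metabolite", "clinical_outcome"),
      relation_type = c("causes", "increases", "increases"),
      polarity = c("harmful", "harmful", "harmful"),
      frequency = c(4L, 3L, 3L),
      duplicates = c(0L, 1L, 0L)
    )
  )
  variants <- tibble(
    normalized = c("Faecalibacterium prausnitzii", "LPS", "high-fat diet"),
    variant = c("F. prausnitzii", "lipopolysaccharide", "high fat diet"),
    n_occurrences = c(4L, 3L, 2L)
  )
  markers <- list(
    marker_set(
      "butanoate_metabolism", external_ref = "KEGG map00650 (synthetic)",
      name = "Fiber Fermentation",
      markers = list(
        "dietary fiber" = character(),
        "Faecalibacterium" = "Faecalibacterium prausnitzii",
        "butyrate" = character(),
        "inflammation" = character(),
        "acetoacetate" = character()
      ),
      expected_edges = tibble(
        source = c("dietary fiber", "Faecalibacterium", "butyrate",
                   "butyrate"),
        target = c("Faecalibacterium", "butyrate", "inflammation",
                   "acetoacetate")
      )
    ),
    marker_set(
      "endotoxemia_cascade", external_ref = "Reactome R-HSA-168898 (synthetic)",
      name = "Inflammation/Immunity",
      markers = list(
        "high-fat diet" = character(),
        "dysbiosis" = character(),
        "LPS" = "lipopolysaccharide",
        "insulin resistance" = character(),
        "TLR4" = character()
      ),
      expected_edges = tibble(
        source = c("high-fat diet", "dysbiosis", "LPS", "LPS"),
        target = c("dysbiosis", "LPS", "insulin resistance", "TLR4")
      )
    )
  )
  synthetic_spec(
    n_documents = 200,
    planted_pathways = list(fiber, hfd),
    variant_table = variants,
    marker_sets = markers,
    n_distractor_edges = 1000,
    n_isolated_mentions = 40,
    seed = seed
  )
}
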