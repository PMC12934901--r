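# The synthetic-corpus generator: determinism, spec validation, and exact
# end-to-end recovery of every manifest quantity by the pipeline.

small_spec <- function(seed = 11) {
  synthetic_spec(
    n_documents = 40,
    planted_pathways = default_synthetic_spec()$planted_pathways,
    variant_table = tibble::tibble(
      normalized = "Faecalibacterium prausnitzii",
      variant = "F. prausnitzii", n_occurrences = 3L
    ),
    n_distractor_edges = 60,
    n_distractor_labels = 25,
    n_isolated_mentions = 8,
    seed = seed
  )
}

test_that("generation is byte-deterministic under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_corpus(small_spec(11), dir = d1)
  generate_corpus(small_spec(11), dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  # a different seed changes the corpus
  d3 <- withr::local_tempdir()
  generate_corpus(small_spec(12), dir = d3)
  same <- purrr::map_lgl(sort(list.files(d3, recursive = TRUE)), function(f) {
    identical(readLines(file.path(d1, f), warn = FALSE),
              readLines(file.path(d3, f), warn = FALSE))
  })
  expect_false(all(same))
})

test_that("spec validation rejects impossible plants and bad mixes", {
  expect_error(
    synthetic_spec(n_documents = 5, planted_edges = tibble::tibble(
      source = "a", source_category = "nutrition",
      target = "b", target_category = "disease",
      relation_type = "affects", frequency = 9L
    )),
    "1 <= F <= n_documents"
  )
  expect_error(
    synthetic_spec(polarity_mix = c(neutral = 0.5, beneficial = 0.4,
                                    harmful = 0.3)),
    "sum to 1"
  )
})

test_that("a single planted triple recovers its closed-form weight", {
  spec <- synthetic_spec(
    n_documents = 10,
    planted_edges = tibble::tibble(
      source = "factor x", source_category = "nutrition",
      target = "response y", target_category = "clinical_outcome",
      relation_type = "affects", polarity = NA_character_, frequency = 9L
    ),
    n_distractor_edges = 0, n_isolated_mentions = 0, seed = 7
  )
  res <- generate_corpus(spec)
  expect_equal(res$manifest$edges$weight, log(10))
  g <- build_graph(res$corpus, res$synonym_map, res$schema)
  expect_equal(round(g$edges$weight, 2), 2.30)
  expect_equal(g$edges$frequency, 9L)
})

test_that("isolated-only corpora prune to an empty graph", {
  spec <- synthetic_spec(n_documents = 10, n_distractor_edges = 0,
                         n_isolated_mentions = 5, seed = 3)
  res <- generate_corpus(spec)
  g <- build_graph(res$corpus, res$synonym_map, res$schema)
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$log$entities_before_pruning, 5)
})

test_that("the pipeline recovers every manifest quantity exactly", {
  dir <- withr::local_tempdir()
  res <- generate_corpus(default_synthetic_spec(seed = 42), dir = dir)
  man <- res$manifest

  # loading the written files reproduces the generator's corpus totals
  corpus <- load_corpus(file.path(dir, "corpus"), res$schema)
  expect_equal(nrow(corpus$mentions), man$totals$mentions)
  expect_equal(nrow(corpus$relations), man$totals$relation_instances)
  expect_equal(attr(corpus, "n_documents"), man$totals$documents)

  syn <- load_synonym_table(file.path(dir, "synonyms.tsv"))
  g <- build_graph(corpus, syn, res$schema)
  expect_equal(nrow(g$nodes), man$nodes_after_pruning)
  expect_equal(nrow(g$edges), man$unique_edges)
  expect_equal(g$log$entities_before_pruning, man$entities_before_pruning)
  expect_equal(g$log$consolidation$mentions_unified,
               man$consolidation$mentions_unified)
  expect_equal(g$log$consolidation$normalized_forms,
               man$consolidation$normalized_forms)

  got <- dplyr::arrange(g$edges, source, target, relation_type)
  want <- dplyr::arrange(man$edges, source, target, relation_type)
  expect_equal(got$source, want$source)
  expect_equal(got$frequency, want$frequency)
  expect_equal(got$instance_count, want$instance_count)
  expect_equal(got$polarity, want$polarity)
  expect_equal(got$weight, want$weight, tolerance = 1e-9)
  expect_identical(got$supporting_docs, want$supporting_docs)

  # planted pathways: docs/rels equal the generator's bookkeeping
  defs <- read_pathway_definitions(file.path(dir, "pathways.json"))
  for (i in seq_along(defs)) {
    ev <- pathway_evidence(g, defs[[i]])
    expect_equal(ev$docs, man$pathways$docs[i])
    expect_equal(ev$rels, man$pathways$rels[i])
    expect_gt(length(extract_chains(g, defs[[i]])), 0)
  }

  # marker-set coverage equals the manifest's ground truth
  sets <- read_marker_sets(file.path(dir, "markers.json"))
  for (i in seq_along(sets)) {
    cov <- edge_coverage(g, sets[[i]])
    expect_equal(cov$C_entity, man$coverage$C_entity[i])
    expect_equal(cov$M_detected, man$coverage$M_detected[i])
    expect_equal(cov$C_edge, man$coverage$C_edge[i])
    expect_equal(cov$R_found, man$coverage$R_found[i])
  }

})

test_that("a planted hub of frequency-rich edges is recovered first", {
  spokes <- sprintf("spoke %02d", 1:6)
  spec <- synthetic_spec(
    n_documents = 60,
    planted_edges = tibble::tibble(
      source = "gut microbiota", source_category = "microbiome",
      target = spokes, target_category = "clinical_outcome",
      relation_type = "affects", polarity = NA_character_,
      frequency = rep(8:9, 3)
    ),
    n_distractor_edges = 50, n_distractor_labels = 40,
    n_isolated_mentions = 0, seed = 19
  )
  res <- generate_corpus(spec)
  g <- build_graph(res$corpus, res$synonym_map, res$schema)
  hubs <- top_hubs(g, 1)
  expect_equal(hubs$label, "gut microbiota")
  expect_equal(top_hubs(g, 1, measure = "degree")$label, "gut microbiota")
})

test_that("distractor polarity shares track the configured mix", {
  spec <- synthetic_spec(n_documents = 200, n_distractor_edges = 1000,
                         n_isolated_mentions = 0, seed = 1)
  res <- generate_corpus(spec)
  mix <- unlist(res$manifest$polarity_mix_realized)
  expect_lt(abs(mix[["neutral"]] * 100 - 62.6), 3)
  expect_lt(abs(mix[["beneficial"]] * 100 - 23.1), 3)
  expect_lt(abs(mix[["harmful"]] * 100 - 14.3), 3)
})
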