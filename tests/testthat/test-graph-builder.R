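# Evidence weighting, edge aggregation, polarity resolution, pruning and
# the full build pipeline, checked against hand counts, a brute-force
# aggregation oracle and the frozen regression fixture.

test_that("the weighting function reproduces the printed worked values", {
  expect_equal(round(compute_edge_weight(9, "neutral"), 2), 2.30)
  expect_equal(round(compute_edge_weight(6, "neutral"), 2), 1.95)
  expect_equal(round(compute_edge_weight(4, "beneficial"), 2), 1.93)
  expect_equal(round(compute_edge_weight(5, "neutral"), 2), 1.79)
  expect_equal(round(compute_edge_weight(4, "harmful"), 2), 1.77)
  expect_equal(round(compute_edge_weight(3, "beneficial"), 2), 1.66)
  expect_equal(round(compute_edge_weight(4, "neutral"), 2), 1.61)
  expect_equal(round(compute_edge_weight(3, "neutral"), 2), 1.39)
  expect_equal(round(compute_edge_weight(1, "neutral"), 3), 0.693)
})

test_that("weights are strictly monotone in F with exact polarity scaling", {
  for (p in c("beneficial", "harmful", "neutral")) {
    w <- compute_edge_weight(1:20, p)
    expect_true(all(diff(w) > 0))
  }
  f <- 1:20
  expect_equal(compute_edge_weight(f, "beneficial") /
                 compute_edge_weight(f, "neutral"),
               rep(1.2, 20), tolerance = 1e-12)
  expect_equal(compute_edge_weight(f, "harmful") /
                 compute_edge_weight(f, "neutral"),
               rep(1.1, 20), tolerance = 1e-12)
})

test_that("an edge requires evidence and a known polarity class", {
  expect_error(compute_edge_weight(0, "neutral"), "positive integer")
  expect_error(compute_edge_weight(-2, "harmful"), "positive integer")
  expect_error(compute_edge_weight(2.5, "neutral"), "positive integer")
  expect_error(compute_edge_weight(3, "ambivalent"), "unknown polarity")
})

test_that("frequency counts unique documents while instances are preserved", {
  # two docs support (fiber, increases, butyrate); one of them twice
  rel <- tibble::tibble(
    doc_id = c("d1", "d2", "d2"),
    source = "fiber", target = "butyrate", relation_type = "increases"
  )
  edges <- aggregate_edges(apply_consolidation(mk_corpus(rel), synonym_map()))
  expect_equal(nrow(edges), 1)
  expect_equal(edges$frequency, 2)
  expect_equal(edges$instance_count, 3)
  expect_equal(edges$supporting_docs[[1]], c("d1", "d2"))
})

test_that("the edge key separates relation types and the empty corpus is empty", {
  rel <- tibble::tibble(
    doc_id = "d1", source = "fiber", target = "butyrate",
    relation_type = c("increases", "affects")
  )
  edges <- aggregate_edges(apply_consolidation(mk_corpus(rel), synonym_map()))
  expect_equal(nrow(edges), 2)
  empty <- apply_consolidation(kg_corpus(), synonym_map())
  expect_equal(nrow(aggregate_edges(empty)), 0)
})

test_that("polarity conflicts resolve by majority with ties to neutral", {
  rel <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    source = "polyphenols", target = "akkermansia",
    relation_type = "affects",
    polarity = c("neutral", "beneficial", "beneficial")
  )
  e <- aggregate_edges(apply_consolidation(mk_corpus(rel), synonym_map()))
  expect_equal(e$polarity, "beneficial")
  expect_true(e$polarity_conflict)

  tie <- aggregate_edges(apply_consolidation(
    mk_corpus(rel[1:2, ]), synonym_map()
  ))
  expect_equal(tie$polarity, "neutral")
})

test_that("self-loops after consolidation are dropped with a warning", {
  sm <- synonym_map(tibble::tibble(
    normalized = "gut microbiota", variant = "intestinal flora"
  ))
  rel <- tibble::tibble(
    doc_id = "d1", source = "gut microbiota", target = "intestinal flora",
    relation_type = "affects"
  )
  expect_warning(g <- build_graph(mk_corpus(rel), sm), "self-loop")
  expect_equal(nrow(g$edges), 0)
})

test_that("build_graph prunes relation-free entities and logs stage counts", {
  corpus <- mk_corpus(tibble::tibble(
    doc_id = "d1",
    source = c("a1", "c1"), target = c("b1", "d1x"),
    relation_type = "affects"
  ))
  # add a fifth entity never used in a relation
  corpus <- kg_corpus(
    dplyr::bind_rows(corpus$mentions, tibble::tibble(
      doc_id = "d1", mention_id = "T99", category = "nutrition",
      surface = "e1", span_start = 100L, span_end = 102L
    )),
    corpus$relations
  )
  g <- build_graph(corpus)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(g$log$entities_before_pruning, 5)
  expect_equal(g$log$entities_after_pruning, 4)
  expect_equal(g$log$relation_instances, 2)
})

test_that("a single relation yields two nodes and one ln(2)-scaled edge", {
  g <- mk_graph(tibble::tibble(
    doc_id = "d1", source = "fiber", target = "butyrate",
    relation_type = "increases"
  ))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, log(2) * 1.2)
})

test_that("aggregation matches a brute-force oracle on random corpora", {
  for (seed in 1:5) {
    rel <- random_rel(seed)
    got <- aggregate_edges(apply_consolidation(mk_corpus(rel), synonym_map()))
    want <- bf_aggregate(rel)
    expect_equal(
      dplyr::select(got, source, target, relation_type, polarity,
                    frequency, instance_count),
      want
    )
    # evidence conservation over the whole corpus
    expect_equal(sum(got$instance_count), nrow(rel))
    expect_lte(sum(got$frequency), nrow(rel))
  }
})

test_that("polarity shares are computed over unique edges", {
  g <- mk_graph(tibble::tibble(
    doc_id = "d1",
    source = c("a1", "b1", "c1"), target = c("b1", "c1", "a1"),
    relation_type = c("benefits", "harms", "affects")
  ))
  expect_equal(polarity_summary(g)$share, c(33.3, 33.3, 33.3))
  g2 <- mk_graph(tibble::tibble(
    doc_id = "d1", source = c("a1", "b1"), target = c("b1", "c1"),
    relation_type = "affects"
  ))
  expect_equal(polarity_summary(g2)$share, c(0, 0, 100))
})

test_that("the regression fixture reproduces its hand-tallied expectations", {
  fx <- regression_fixture()
  ex <- fx$expected
  g <- build_graph(fx$corpus, fx$synonym_map, fx$schema)

  expect_equal(g$log$documents, ex$totals$documents)
  expect_equal(g$log$mentions, ex$totals$mentions)
  expect_equal(g$log$relation_instances, ex$totals$relation_instances)
  expect_equal(g$log$consolidation$mentions_unified,
               ex$consolidation$mentions_unified)
  expect_equal(g$log$consolidation$normalized_forms,
               ex$consolidation$normalized_forms)
  expect_equal(g$log$consolidation$share_unified,
               ex$consolidation$share_unified)
  expect_equal(nrow(g$nodes), ex$nodes_after_pruning)
  expect_equal(g$log$entities_before_pruning, ex$entities_before_pruning)
  expect_equal(nrow(g$edges), ex$unique_edges)

  want <- tibble::as_tibble(ex$edges) |>
    dplyr::arrange(source, target, relation_type)
  got <- g$edges |>
    dplyr::mutate(docs = purrr::map_chr(supporting_docs, paste,
                                        collapse = ";")) |>
    dplyr::arrange(source, target, relation_type)
  expect_equal(got$source, want$source)
  expect_equal(got$target, want$target)
  expect_equal(got$relation_type, want$relation_type)
  expect_equal(got$polarity, want$polarity)
  expect_equal(got$frequency, want$frequency)
  expect_equal(got$instance_count, want$instance_count)
  expect_equal(got$weight, want$weight, tolerance = 1e-9)
  expect_equal(got$docs, want$docs)
  expect_equal(got$polarity_conflict, !is.na(want$conflict) & want$conflict)

  ps <- polarity_summary(g)
  expect_equal(ps$n, unlist(ex$polarity_counts[ps$polarity],
                            use.names = FALSE))
  expect_equal(ps$share, unlist(ex$polarity_shares[ps$polarity],
                                use.names = FALSE))
})
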