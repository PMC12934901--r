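# Keyword matching, pathway evidence metrics and stage-ordered chain
# extraction.

test_that("keyword matching is whole-word and case-insensitive", {
  labels <- c("butyrate", "butyrate production", "butyrogenesis",
              "Faecalibacterium prausnitzii", "heart", "art therapy")
  expect_equal(matches_keyword(labels, "butyrate"),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(matches_keyword("Faecalibacterium prausnitzii",
                              "faecalibacterium"))
  expect_false(matches_keyword("heart", "art"))
  expect_true(matches_keyword("art therapy", "art"))
  expect_true(matches_keyword("high-fat diet", "high-fat diet"))
})

test_that("match_entities returns matching node labels and rejects empty input", {
  fx <- regression_fixture()
  g <- build_graph(fx$corpus, fx$synonym_map, fx$schema)
  expect_equal(match_entities(g, "Faecalibacterium"),
               "Faecalibacterium prausnitzii")
  expect_equal(match_entities(g, "no such keyword"), character())
  expect_error(match_entities(g, character()), "non-empty")
})

test_that("evidence pools unique documents and relation instances", {
  # three stage-consistent edges with docs {d1,d2}, {d2}, {d3} and
  # instance counts 2, 1, 1 -> 3 unique docs, 4 instances
  rel <- tibble::tibble(
    doc_id = c("d1", "d2", "d2", "d3"),
    source = c("fiber", "fiber", "microbe x", "metab y"),
    target = c("microbe x", "microbe x", "metab y", "outcome z"),
    relation_type = "increases"
  )
  g <- mk_graph(rel)
  def <- pathway_definition(
    "p", stages = list(diet = "fiber", microbiome = "microbe x",
                       metabolite = "metab y", outcome = "outcome z"),
    polarity_claim = "beneficial"
  )
  ev <- pathway_evidence(g, def)
  expect_equal(ev$docs, 3)
  expect_equal(ev$rels, 4)
  expect_equal(nrow(ev$matched_edges), 3)
})

test_that("edges running against stage order are excluded", {
  rel <- tibble::tibble(
    doc_id = "d1",
    source = c("fiber", "outcome z"),
    target = c("outcome z", "fiber"),
    relation_type = "affects"
  )
  g <- mk_graph(rel)
  def <- pathway_definition(
    "p", stages = list(diet = "fiber", outcome = "outcome z"),
    polarity_claim = "beneficial"
  )
  ev <- pathway_evidence(g, def)
  expect_equal(nrow(ev$matched_edges), 1)
  expect_equal(ev$matched_edges$source, "fiber")
})

test_that("an unmatched definition yields all-zero metrics, not an error", {
  fx <- regression_fixture()
  g <- build_graph(fx$corpus, fx$synonym_map, fx$schema)
  def <- pathway_definition(
    "none", stages = list(diet = "astronaut food", outcome = "weightlessness"),
    polarity_claim = "beneficial"
  )
  ev <- pathway_evidence(g, def)
  expect_equal(ev$docs, 0)
  expect_equal(ev$rels, 0)
  empty <- pathway_evidence(build_graph(kg_corpus()), def)
  expect_equal(empty$docs, 0)
})

test_that("adding keywords never decreases evidence", {
  fx <- regression_fixture()
  g <- build_graph(fx$corpus, fx$synonym_map, fx$schema)
  base <- pathway_definition(
    "p", stages = list(diet = "fiber", outcome = "inflammation"),
    polarity_claim = "beneficial"
  )
  grown <- pathway_definition(
    "p", stages = list(diet = c("fiber", "high-fat diet"),
                       outcome = c("inflammation", "endotoxemia", "LPS")),
    polarity_claim = "beneficial"
  )
  ev0 <- pathway_evidence(g, base)
  ev1 <- pathway_evidence(g, grown)
  expect_gte(ev1$docs, ev0$docs)
  expect_gte(ev1$rels, ev0$rels)
  # global bounds
  expect_lte(ev1$docs, dplyr::n_distinct(fx$corpus$mentions$doc_id))
  expect_lte(ev1$rels, nrow(fx$corpus$relations))
})

test_that("chains follow stage order from diet to outcome and carry evidence", {
  fx <- regression_fixture()
  g <- build_graph(fx$corpus, fx$synonym_map, fx$schema)

  ch <- extract_chains(g, fx$pathways[[1]])
  expect_length(ch, fx$expected$pathways$n_chains[1])
  expect_equal(ch[[1]]$nodes, fx$expected$pathways$chain_nodes[[1]])
  expect_equal(ch[[1]]$stages,
               c("diet", "microbiome", "metabolite", "outcome"))
  expect_equal(nrow(ch[[1]]$edges), 3)

  ch2 <- extract_chains(g, fx$pathways[[2]])
  expect_length(ch2, fx$expected$pathways$n_chains[2])
  expect_equal(ch2[[1]]$nodes, fx$expected$pathways$chain_nodes[[2]])

  # every chain edge appears in the pathway's matched edges
  for (k in 1:2) {
    ev <- pathway_evidence(g, fx$pathways[[k]])
    key <- function(e) paste(e$source, e$target, e$relation_type)
    chains <- extract_chains(g, fx$pathways[[k]])
    for (chain in chains) {
      expect_true(all(key(chain$edges) %in% key(ev$matched_edges)))
    }
  }
})

test_that("chain extraction guards its inputs and degenerate graphs", {
  fx <- regression_fixture()
  g <- build_graph(fx$corpus, fx$synonym_map, fx$schema)
  expect_error(extract_chains(g, fx$pathways[[1]], max_path_len = 1),
               "max_path_len")
  no_diet <- pathway_definition(
    "p", stages = list(diet = "astronaut food", outcome = "inflammation"),
    polarity_claim = "beneficial"
  )
  expect_length(extract_chains(g, no_diet), 0)
})

test_that("chain rendering decorates targets by edge polarity", {
  fx <- regression_fixture()
  g <- build_graph(fx$corpus, fx$synonym_map, fx$schema)
  ch <- extract_chains(g, fx$pathways[[1]])[[1]]
  txt <- render_chain(ch)
  expect_match(txt, "^fiber ")
  expect_match(txt, "inflammation", fixed = TRUE)
  expect_match(txt, "↑")  # beneficial edges render an up arrow
})

test_that("pathway definitions validate their stages and JSON round-trips", {
  expect_error(pathway_definition("p", stages = list(diet = "x"),
                                  polarity_claim = "beneficial"),
               "at least 2 stages")
  expect_error(pathway_definition(
    "p", stages = list(diet = "x", dessert = "y"),
    polarity_claim = "beneficial"
  ), "unknown stage roles")
  path <- system.file("extdata", "pathways.json", package = "nutrikg")
  defs <- read_pathway_definitions(path)
  expect_length(defs, 4)
  expect_equal(defs[[1]]$pathway_id, "fiber_scfa_inflammation")
  expect_equal(names(defs[[1]]$stages),
               c("diet", "microbiome", "metabolite", "outcome"))
})
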