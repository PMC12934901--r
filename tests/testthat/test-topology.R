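# Degrees, hubs, clustering, density and category connectivity, including
# brute-force cross-checks on small random graphs.

test_that("degrees count incident edges on the directed multigraph", {
  g <- mk_graph(tibble::tibble(
    doc_id = "d1", source = c("a1", "b1"), target = c("b1", "c1"),
    relation_type = "affects"
  ))
  deg <- degree_table(g)
  expect_equal(setNames(deg$degree, deg$label)[c("a1", "b1", "c1")],
               c(a1 = 1L, b1 = 2L, c1 = 1L))
  expect_equal(sum(deg$degree), 2 * nrow(g$edges))
})

test_that("a star hub accumulates the weighted degree of its spokes", {
  g <- mk_graph(tibble::tibble(
    doc_id = "d1", source = "hub",
    target = c("s1", "s2", "s3", "s4"), relation_type = "affects"
  ))
  deg <- degree_table(g)
  expect_equal(deg$label[1], "hub")
  expect_equal(deg$weighted_degree[1], 4 * log(2))
  expect_equal(round(deg$weighted_degree[1], 3), 2.773)
})

test_that("degree tables agree with brute-force incidence counts", {
  for (seed in c(3, 9)) {
    rel <- random_rel(seed, n_docs = 8, n_labels = 10, n_inst = 40)
    g <- mk_graph(rel)
    deg <- degree_table(g)
    for (i in seq_len(nrow(deg))) {
      expect_equal(
        deg$degree[i],
        sum(g$edges$source == deg$label[i]) +
          sum(g$edges$target == deg$label[i])
      )
      expect_equal(
        deg$weighted_degree[i],
        sum(g$edges$weight[g$edges$source == deg$label[i]]) +
          sum(g$edges$weight[g$edges$target == deg$label[i]])
      )
    }
    # default-multiplier lower bound: every edge weighs at least ln 2
    expect_true(all(deg$weighted_degree >= log(2) * deg$degree - 1e-9))
    expect_equal(sum(deg$degree), 2 * nrow(g$edges))
  }
})

test_that("hubs rank by the chosen measure with alphabetical tie-breaks", {
  g <- mk_graph(tibble::tibble(
    doc_id = "d1",
    source = c("x1", "x1", "x1", "beta", "alpha"),
    target = c("p1", "q1", "r1", "p1", "q1"),
    relation_type = "affects"
  ))
  hubs <- top_hubs(g, 3, measure = "degree")
  expect_equal(hubs$label[1], "x1")
  # alpha and beta tie at degree 1; alphabetical order breaks the tie
  tied <- top_hubs(g, nrow(g$nodes), measure = "degree")
  expect_lt(which(tied$label == "alpha"), which(tied$label == "beta"))
  expect_equal(nrow(top_hubs(g, 100)), nrow(g$nodes))
  expect_error(top_hubs(g, 0), "k must be")
})

test_that("triangle and star clustering/density match the closed forms", {
  tri <- mk_graph(tibble::tibble(
    doc_id = "d1", source = c("a1", "b1", "c1"),
    target = c("b1", "c1", "a1"), relation_type = "affects"
  ))
  cd <- clustering_and_density(tri)
  expect_equal(cd$clustering, 1)
  expect_equal(cd$density, 1)

  star <- mk_graph(tibble::tibble(
    doc_id = "d1", source = "hub", target = c("s1", "s2", "s3", "s4"),
    relation_type = "affects"
  ))
  expect_equal(clustering_and_density(star)$clustering, 0)

  one <- mk_graph(tibble::tibble(
    doc_id = "d1", source = "a1", target = "b1", relation_type = "affects"
  ))
  one$nodes <- one$nodes[1, ]
  expect_error(clustering_and_density(one), "fewer than 2")
})

test_that("clustering and density match brute force on small random graphs", {
  for (seed in 1:12) {
    rel <- random_rel(seed, n_docs = 3, n_labels = 8, n_inst = 14)
    if (nrow(rel) == 0) next
    g <- mk_graph(rel)
    cd <- clustering_and_density(g)
    pairs <- tibble::tibble(
      a = pmin(g$edges$source, g$edges$target),
      b = pmax(g$edges$source, g$edges$target)
    ) |> dplyr::distinct()
    want <- bf_clustering_density(g$nodes$label, pairs)
    expect_equal(cd$clustering, want$clustering, tolerance = 1e-12)
    expect_equal(cd$density, want$density, tolerance = 1e-12)
    expect_gte(cd$density, 0); expect_lte(cd$density, 1)
    expect_gte(cd$clustering, 0); expect_lte(cd$clustering, 1)
  }
})

test_that("parallel edges of different types collapse in the projection", {
  g <- mk_graph(tibble::tibble(
    doc_id = "d1", source = "a1", target = "b1",
    relation_type = c("affects", "increases", "benefits")
  ))
  expect_equal(clustering_and_density(g)$density, 1)
})

test_that("the category-connectivity matrix counts and normalizes edge pairs", {
  rel <- tibble::tibble(
    doc_id = "d1",
    source = c("f1", "f2", "f3", "m1"),
    target = c("o1", "o1", "o2", "f1"),
    relation_type = "affects"
  )
  corpus <- mk_corpus(rel)
  cat_of <- c(f1 = "nutrition", f2 = "nutrition", f3 = "nutrition",
              m1 = "microbiome", o1 = "clinical_outcome",
              o2 = "clinical_outcome")
  corpus$mentions$category <- unname(cat_of[corpus$mentions$surface])
  g <- build_graph(corpus)
  mat <- category_connectivity(g, "max")
  expect_equal(mat["nutrition", "clinical_outcome"], 1)
  expect_equal(mat["clinical_outcome", "nutrition"], 1)
  expect_equal(mat["microbiome", "nutrition"], 1 / 3, tolerance = 1e-12)
  rowmat <- category_connectivity(g, "row")
  expect_equal(unname(rowSums(rowmat)[rowSums(rowmat) > 0]),
               rep(1, sum(rowSums(rowmat) > 0)))

  empty <- build_graph(kg_corpus())
  expect_equal(dim(category_connectivity(empty)), c(0, 0))
})

test_that("the topology report bundles all statistics coherently", {
  fx <- regression_fixture()
  g <- build_graph(fx$corpus, fx$synonym_map, fx$schema)
  rep <- topology_report(g, k = 3)
  expect_equal(rep$hubs$label[1], fx$expected$top_weighted_hub$label)
  expect_equal(rep$hubs$weighted_degree[1],
               fx$expected$top_weighted_hub$weighted_degree,
               tolerance = 1e-9)
  expect_equal(rep$hubs$degree[1], fx$expected$top_weighted_hub$degree)
  gl <- glance(rep)
  expect_equal(gl$nodes, nrow(g$nodes))
  expect_true(gl$density > 0 && gl$density <= 1)
})
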