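# Test helpers: compact corpus construction and brute-force oracles kept
# deliberately independent of the package's aggregation/topology code paths.

# Build a kg_corpus from a relation table (doc_id, source, target,
# relation_type, optional polarity); every relation instance gets a fresh
# mention pair, all categorised `category`.
mk_corpus <- function(rel, category = "nutrition", schema = kg_schema()) {
  rel <- tibble::as_tibble(rel)
  if (!"polarity" %in% names(rel)) rel$polarity <- NA_character_
  rel$polarity <- ifelse(
    is.na(rel$polarity),
    unname(schema$type_to_polarity[rel$relation_type]),
    rel$polarity
  )
  mentions <- list()
  relations <- list()
  for (d in unique(rel$doc_id)) {
    rd <- rel[rel$doc_id == d, , drop = FALSE]
    pos <- 0L
    for (i in seq_len(nrow(rd))) {
      s <- rd$source[i]; t <- rd$target[i]
      mentions[[length(mentions) + 1]] <- tibble::tibble(
        doc_id = d, mention_id = paste0("T", 2 * i - 1), category = category,
        surface = s, span_start = pos, span_end = pos + nchar(s)
      )
      pos <- pos + nchar(s) + 1L
      mentions[[length(mentions) + 1]] <- tibble::tibble(
        doc_id = d, mention_id = paste0("T", 2 * i), category = category,
        surface = t, span_start = pos, span_end = pos + nchar(t)
      )
      pos <- pos + nchar(t) + 1L
      relations[[length(relations) + 1]] <- tibble::tibble(
        doc_id = d, relation_id = paste0("R", i),
        relation_type = rd$relation_type[i], polarity = rd$polarity[i],
        source_mention = paste0("T", 2 * i - 1),
        target_mention = paste0("T", 2 * i)
      )
    }
  }
  kg_corpus(dplyr::bind_rows(mentions), dplyr::bind_rows(relations),
            schema = schema)
}

mk_graph <- function(rel, ...) build_graph(mk_corpus(rel, ...))

# Brute-force edge aggregation: plain loops over every (source, target,
# type) triple, independent of dplyr grouping.
bf_aggregate <- function(rel, schema = kg_schema()) {
  if (!"polarity" %in% names(rel)) rel$polarity <- NA_character_
  rel$polarity <- ifelse(
    is.na(rel$polarity),
    unname(schema$type_to_polarity[rel$relation_type]),
    rel$polarity
  )
  key <- paste(rel$source, rel$target, rel$relation_type, sep = "\r")
  out <- list()
  for (k in sort(unique(key))) {
    sel <- key == k
    pols <- rel$polarity[sel]
    tab <- table(pols)
    top <- names(tab)[tab == max(tab)]
    out[[k]] <- tibble::tibble(
      source = rel$source[sel][1], target = rel$target[sel][1],
      relation_type = rel$relation_type[sel][1],
      polarity = if (length(top) > 1) "neutral" else top,
      frequency = length(unique(rel$doc_id[sel])),
      instance_count = sum(sel)
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), source, target, relation_type)
}

# Brute-force undirected clustering and density from an explicit pair list.
bf_clustering_density <- function(labels, pairs) {
  n <- length(labels)
  A <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$a[i] == pairs$b[i]) next
    A[pairs$a[i], pairs$b[i]] <- 1L
    A[pairs$b[i], pairs$a[i]] <- 1L
  }
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    links <- 0L
    for (x in nb) for (y in nb) if (x < y && A[x, y] == 1L) links <- links + 1L
    cc[v] <- 2 * links / (k * (k - 1))
  }
  list(clustering = mean(cc), density = sum(A) / 2 / (n * (n - 1) / 2))
}

# Random relation tables for property-style tests.
random_rel <- function(seed, n_docs = 6, n_labels = 6, n_inst = 25) {
  withr::with_seed(seed, {
    labels <- paste0("node", letters[seq_len(n_labels)])
    types <- c("increases", "reduces", "affects", "benefits")
    tibble::tibble(
      doc_id = sample(paste0("d", seq_len(n_docs)), n_inst, replace = TRUE),
      source = sample(labels, n_inst, replace = TRUE),
      target = sample(labels, n_inst, replace = TRUE),
      relation_type = sample(types, n_inst, replace = TRUE)
    ) |> dplyr::filter(source != target)
  })
}
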