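# Synonym consolidation: expert-curated merging of lexically variant and
# synonymous entity labels into normalized forms before edge aggregation.

#' Construct a synonym map
#'
#' A synonym map is a curated table of normalized labels and their variant
#' surface forms, plus the lexical matching options applied before lookup.
#' Two invariants are enforced: a variant never maps to two different
#' normalized labels, and a normalized label is never itself a variant of
#' another entry (no chains).
#'
#' @param entries Tibble/data frame with columns `normalized` and `variant`.
#' @param case_fold Fold case before matching (and in pass-through output).
#' @param whitespace_collapse Collapse internal runs of whitespace.
#' @param strip_parenthetical Strip a single trailing parenthetical group of
#'   at most 10 characters, e.g. an abbreviation: "Mediterranean diet (MD)".
#' @return A `kg_synonym_map`.
#' @examples
#' synonym_map(tibble::tibble(
#'   normalized = "short-chain fatty acids", variant = "SCFA"
#' ))
#' @export
synonym_map <- function(entries = tibble(normalized = character(),
                                         variant = character()),
                        case_fold = TRUE, whitespace_collapse = TRUE,
                        strip_parenthetical = TRUE) {
  entries <- as_tibble(entries)[, c("normalized", "variant")]
  opts <- list(case_fold = case_fold,
               whitespace_collapse = whitespace_collapse,
               strip_parenthetical = strip_parenthetical)
  lex <- function(x) lexical_normalize(x, opts)
  vkey <- lex(entries$variant)
  nkey <- lex(entries$normalized)
  conflict <- tibble(vkey = vkey, normalized = entries$normalized) |>
    distinct() |> count(.data$vkey) |> filter(n > 1)
  if (nrow(conflict) > 0) {
    offenders <- entries[lex(entries$variant) %in% conflict$vkey, ]
    abort(paste0(
      "variant mapped to multiple normalized labels:\n  ",
      paste(paste0(offenders$variant, " -> ", offenders$normalized),
            collapse = "\n  ")
    ))
  }
  chained <- intersect(unique(nkey), unique(vkey))
  if (length(chained) > 0) {
    abort(paste0(
      "synonym chain: normalized label also listed as a variant: ",
      paste(chained, collapse = ", ")
    ))
  }
  structure(
    list(entries = distinct(entries), options = opts),
    class = "kg_synonym_map"
  )
}

#' @export
print.kg_synonym_map <- function(x, ...) {
  cat("<kg_synonym_map>", nrow(x$entries), "variants ->",
      n_distinct(x$entries$normalized), "normalized forms\n")
  invisible(x)
}

#' Load a synonym table from TSV
#'
#' Expects two columns, `normalized_label` and `variant_label` (a header is
#' required); `#` comment lines are permitted. The table is validated
#' against the no-conflict and no-chain invariants.
#'
#' @param path Path to the TSV file.
#' @inheritParams synonym_map
#' @return A `kg_synonym_map`.
#' @export
load_synonym_table <- function(path, case_fold = TRUE,
                               whitespace_collapse = TRUE,
                               strip_parenthetical = TRUE) {
  if (!file.exists(path)) abort(paste0("synonym table not found: ", path))
  tbl <- readr::read_tsv(path, col_types = "cc", comment = "#")
  names(tbl) <- c("normalized", "variant")
  synonym_map(tbl, case_fold = case_fold,
              whitespace_collapse = whitespace_collapse,
              strip_parenthetical = strip_parenthetical)
}

lexical_normalize <- function(x, opts) {
  x <- trimws(x)
  if (isTRUE(opts$strip_parenthetical)) {
    x <- sub("\\s*\\([^()]{1,10}\\)$", "", x)
  }
  if (isTRUE(opts$whitespace_collapse)) {
    x <- gsub("[[:space:]]+", " ", x)
  }
  if (isTRUE(opts$case_fold)) x <- tolower(x)
  x
}

#' Normalize an entity label
#'
#' Applies the map's lexical options (case folding, whitespace collapsing,
#' trailing-parenthetical stripping), then looks the result up in the
#' synonym table. A label matching a variant returns that variant's
#' normalized form; a label matching a normalized form returns it in the
#' table's canonical casing; anything else passes through lexically
#' normalized. Matching is exact on the lexically normalized string — never
#' fuzzy — so only curated merges happen.
#'
#' @param surface Character vector of surface labels.
#' @param map A `kg_synonym_map`.
#' @return Character vector of normalized labels.
#' @examples
#' sm <- synonym_map(tibble::tibble(
#'   normalized = "short-chain fatty acids", variant = "SCFA"
#' ))
#' normalize_label(c("SCFA", "butyrate"), sm)
#' @export
normalize_label <- function(surface, map = synonym_map()) {
  normalize_label_impl(surface, map)$label
}

# label plus whether the change came through the synonym table (a variant
# lookup whose normalized form differs lexically from the variant) — pure
# case/whitespace/parenthetical normalization is not a table-driven merge
normalize_label_impl <- function(surface, map) {
  opts <- map$options
  lex <- lexical_normalize(surface, opts)
  vkey <- lexical_normalize(map$entries$variant, opts)
  nkey <- lexical_normalize(map$entries$normalized, opts)
  out <- lex
  iv <- match(lex, vkey)
  hit_v <- !is.na(iv)
  out[hit_v] <- map$entries$normalized[iv[hit_v]]
  im <- match(lex, nkey)
  hit_n <- !hit_v & !is.na(im)
  out[hit_n] <- map$entries$normalized[im[hit_n]]
  list(
    label = out,
    via_table = hit_v & lexical_normalize(out, opts) != lex
  )
}

#' Apply synonym consolidation to a corpus
#'
#' Rewrites every mention's label to its normalized form and reports how
#' much consolidation the table achieved. The mention count never changes
#' and the number of distinct labels never increases; the operation is
#' idempotent. "Unified" mentions are those whose label changed through the
#' synonym table (pure case/whitespace/parenthetical normalization does not
#' count), and `normalized_forms` is the number of distinct normalized
#' labels they were merged into.
#'
#' @param corpus A `kg_corpus`.
#' @param map A `kg_synonym_map`.
#' @return The corpus with a `label` column added to `mentions`, and a
#'   `consolidation` attribute of class `kg_consolidation_report`
#'   (mentions_unified, normalized_forms, share_unified in percent).
#' @export
apply_consolidation <- function(corpus, map = synonym_map()) {
  m <- corpus$mentions
  # always recompute from the original surface so the operation is idempotent
  base <- m$surface
  res <- normalize_label_impl(base, map)
  label <- res$label
  unified <- res$via_table
  m$label <- label
  total <- nrow(m)
  report <- structure(
    list(
      mentions_unified = sum(unified),
      normalized_forms = n_distinct(label[unified]),
      share_unified = if (total == 0) 0 else
        round_half_up(sum(unified) / total * 100, 1)
    ),
    class = "kg_consolidation_report"
  )
  out <- new_corpus(m, corpus$relations)
  attr(out, "consolidation") <- report
  out
}

#' @export
print.kg_consolidation_report <- function(x, ...) {
  cat("<kg_consolidation_report> unified", x$mentions_unified,
      "mentions (", paste0(x$share_unified, "%"), ") into",
      x$normalized_forms, "normalized forms\n")
  invisible(x)
}
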