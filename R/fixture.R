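# A fixed, hand-computable 12-document corpus used as a regression anchor.
# Its expected counts live in inst/extdata/regression_expected.json and were
# tallied by hand from the annotation lines below; the fixture exercises
# synonym consolidation (three variant groups), pruning (two isolated
# entities), one beneficial and one harmful mechanistic chain, polarity
# overrides, within-document duplicate instances, and a polarity-conflict
# triple (one neutral vs one beneficial instance, resolved neutral by the
# tie rule).

fixture_ann <- function() {
  list(
    d01 = c(
      "T1\tnutrition 0 5\tfiber",
      "T2\tmicrobiome 6 34\tFaecalibacterium prausnitzii",
      "T3\tnutrition 35 40\tfiber",
      "T4\tmicrobiome 41 69\tFaecalibacterium prausnitzii",
      "R1\tincreases Arg1:T1 Arg2:T2",
      "R2\tincreases Arg1:T3 Arg2:T4"
    ),
    d02 = c(
      "T1\tnutrition 0 5\tfiber",
      "T2\tmicrobiome 6 34\tFaecalibacterium prausnitzii",
      "T3\tmetabolite 35 43\tbutyrate",
      "R1\tincreases Arg1:T1 Arg2:T2",
      "R2\tincreases Arg1:T2 Arg2:T3"
    ),
    d03 = c(
      "T1\tnutrition 0 5\tfiber",
      "T2\tmicrobiome 6 34\tFaecalibacterium prausnitzii",
      "T3\tmetabolite 35 43\tbutyrate",
      "T4\tclinical_outcome 44 56\tinflammation",
      "R1\tincreases Arg1:T1 Arg2:T2",
      "R2\tincreases Arg1:T2 Arg2:T3",
      "R3\treduces Arg1:T3 Arg2:T4",
      "A1\tPolarity R3 beneficial"
    ),
    d04 = c(
      "T1\tmetabolite 0 8\tbutyrate",
      "T2\tclinical_outcome 9 21\tinflammation",
      "T3\tnutrition 22 30\tcollagen",
      "R1\treduces Arg1:T1 Arg2:T2",
      "A1\tPolarity R1 beneficial"
    ),
    d05 = c(
      "T1\tnutrition 0 13\thigh-fat diet",
      "T2\tmetabolite 14 17\tLPS",
      "R1\tincreases Arg1:T1 Arg2:T2",
      "A1\tPolarity R1 harmful"
    ),
    d06 = c(
      "T1\tnutrition 0 13\thigh-fat diet",
      "T2\tmetabolite 14 17\tLPS",
      "T3\tclinical_outcome 18 30\tendotoxemia",
      "R1\tincreases Arg1:T1 Arg2:T2",
      "R2\tcauses Arg1:T2 Arg2:T3",
      "A1\tPolarity R1 harmful"
    ),
    d07 = c(
      "T1\tclinical_outcome 0 11\tendotoxemia",
      "T2\tclinical_outcome 12 30\tinsulin resistance",
      "R1\tincreases Arg1:T1 Arg2:T2",
      "A1\tPolarity R1 harmful"
    ),
    d08 = c(
      "T1\tnutrition 0 11\tpolyphenols",
      "T2\tmicrobiome 12 35\tAkkermansia muciniphila",
      "R1\taffects Arg1:T1 Arg2:T2"
    ),
    d09 = c(
      "T1\tnutrition 0 11\tpolyphenols",
      "T2\tmicrobiome 12 35\tAkkermansia muciniphila",
      "R1\taffects Arg1:T1 Arg2:T2",
      "A1\tPolarity R1 beneficial"
    ),
    d10 = c(
      "T1\tnutrition 0 13\tmediterranean",
      "T2\tmicrobiome 14 30\tintestinal flora",
      "R1\tbenefits Arg1:T1 Arg2:T2"
    ),
    d11 = c(
      "T1\tnutrition 0 18\tMediterranean diet",
      "T2\tmicrobiome 19 33\tgut microbiome",
      "T3\tmetabolite 34 38\tSCFA",
      "T4\tphysiological_process 39 56\timmune regulation",
      "R1\tbenefits Arg1:T1 Arg2:T2",
      "R2\tbenefits Arg1:T3 Arg2:T4"
    ),
    d12 = c(
      "T1\tmetabolite 0 5\tSCFAs",
      "T2\tphysiological_process 6 23\timmune regulation",
      "T3\tnutrition 24 33\tvitamin D",
      "R1\tbenefits Arg1:T1 Arg2:T2"
    )
  )
}

#' Hand-computable regression fixture
#'
#' A deterministic 12-document corpus whose expected pipeline results were
#' tallied by hand and frozen in
#' `system.file("extdata", "regression_expected.json", package = "nutrikg")`.
#' It exercises consolidation (three variant groups: Mediterranean diet,
#' gut microbiota, short-chain fatty acids), pruning (two isolated
#' entities: collagen, vitamin D), one beneficial chain
#' (fiber -> Faecalibacterium prausnitzii -> butyrate -> inflammation),
#' one harmful chain (high-fat diet -> LPS -> endotoxemia -> insulin
#' resistance), and a polarity-conflict triple
#' (polyphenols -affects-> Akkermansia muciniphila, neutral vs beneficial,
#' tie resolved neutral).
#'
#' @param dir Optional directory; when given, the fixture's .ann files and
#'   synonym table are written there (`corpus/`, `synonyms.tsv`).
#' @return List with `corpus`, `synonym_map`, `pathways` (the two chain
#'   definitions), `schema`, and `expected` (the frozen expectations).
#' @export
regression_fixture <- function(dir = NULL) {
  schema <- kg_schema()
  anns <- fixture_ann()
  docs <- purrr::imap(anns, ~ parse_standoff(.x, doc_id = .y, schema = schema,
                                             strict = TRUE))
  corpus <- new_corpus(
    bind_rows(purrr::map(docs, "mentions")),
    bind_rows(purrr::map(docs, "relations"))
  )
  # the last three entries pin the canonical casing of mixed-case labels
  # (pass-through labels are otherwise case-folded); their variants do not
  # occur in the fixture, so they add no unified mentions
  syn <- synonym_map(tibble(
    normalized = c("short-chain fatty acids", "short-chain fatty acids",
                   "gut microbiota", "gut microbiota",
                   "Mediterranean diet",
                   "Faecalibacterium prausnitzii", "Akkermansia muciniphila",
                   "LPS"),
    variant = c("SCFA", "SCFAs",
                "intestinal flora", "gut microbiome",
                "mediterranean",
                "F. prausnitzii", "A. muciniphila",
                "lipopolysaccharide")
  ))
  pathways <- list(
    pathway_definition(
      "fiber_axis", "Fiber-SCFA-Inflammation", "beneficial",
      stages = list(
        diet = "fiber",
        microbiome = "Faecalibacterium",
        metabolite = "butyrate",
        outcome = "inflammation"
      )
    ),
    pathway_definition(
      "hfd_axis", "High-Fat-LPS-Metabolic Dysfunction", "harmful",
      stages = list(
        diet = "high-fat diet",
        metabolite = "LPS",
        outcome = c("endotoxemia", "insulin resistance")
      )
    )
  )
  expected <- jsonlite::fromJSON(
    system.file("extdata", "regression_expected.json", package = "nutrikg"),
    simplifyDataFrame = TRUE
  )
  out <- list(corpus = corpus, synonym_map = syn, pathways = pathways,
              schema = schema, expected = expected)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "corpus"), showWarnings = FALSE,
               recursive = TRUE)
    for (d in names(anns)) {
      writeLines(anns[[d]], file.path(dir, "corpus", paste0(d, ".ann")),
                 useBytes = TRUE)
    }
    readr::write_tsv(
      syn$entries |>
        select(normalized_label = "normalized", variant_label = "variant"),
      file.path(dir, "synonyms.tsv")
    )
    out$paths <- list(corpus = file.path(dir, "corpus"),
                      synonyms = file.path(dir, "synonyms.tsv"))
  }
  out
}
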