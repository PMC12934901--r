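Package: nutrikg
Title: Evidence-Weighted Diet-Microbiome-Health Knowledge Graphs from
    Annotated Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds polarity-aware knowledge graphs of diet, gut-microbiome
    and host-health mechanisms from manually annotated abstracts. Parses
    brat-style standoff annotation files, consolidates lexically variant
    entity labels through a curated synonym table, aggregates relation
    instances into unique directed edges weighted by ln(F+1) x P (evidence
    frequency across unique abstracts, scaled by a polarity multiplier),
    characterises network topology (degrees, hubs, clustering, density,
    category connectivity), aggregates keyword-defined mechanistic-pathway
    evidence, and validates entity and edge coverage against curated pathway
    marker sets. Includes a seeded synthetic-corpus generator with a
    ground-truth manifest so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
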