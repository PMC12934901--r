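---
title: "Methods: evidence-weighted diet-microbiome-health knowledge graphs"
author: "nutrikg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-weighted diet-microbiome-health knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrikg)
```

## The problem and the model

Mechanistic links between dietary exposures, gut microbes, microbial
metabolites and host outcomes are scattered across thousands of abstracts,
most of which report a single association. `nutrikg` turns manually
annotated abstracts — entity mentions and directed, polarity-labelled
relation instances in brat-style standoff files — into a single directed
knowledge graph in which each unique (source, target, relation-type) triple
is one edge carrying its accumulated evidence.

The central quantity is the composite edge weight

$$W = \ln(F + 1) \times P,$$

where $F$ is the **evidence frequency**: the number of *distinct* abstracts
(unique document identifiers) supporting the triple, not the number of
relation instances; and $P$ is a **polarity multiplier** — 1.2 for
beneficial, 1.1 for harmful, 1.0 for neutral/observational relationships.
The logarithm damps high-frequency associations so that a handful of
heavily repeated correlative findings cannot drown out moderately supported
mechanistic ones, while the multiplier gives directional (beneficial or
harmful) evidence a modest premium over purely observational co-mention.
The natural logarithm is used throughout; with it, a neutral edge supported
by nine abstracts weighs $\ln 10 = 2.30$ and a singleton neutral edge
weighs $\ln 2 = 0.693$.

Both $F \ge 1$ and $P > 0$ are enforced: an edge cannot exist without at
least one supporting document.

## Pipeline stages and their rules

### Parsing

`parse_standoff()` reads `T` (entity mention), `R` (relation) and `A`
(polarity attribute) records. Character offsets are 0-based and half-open,
the brat convention. Polarity resolution order: an explicit `A` record
beats the relation type's default class (benefits/increases are beneficial
by default; reduces/inhibits/harms harmful; the remaining seven types
neutral). Malformed lines are always fatal with a line number; *schema*
violations (unknown category or type, dangling endpoints, self-referential
relations) are collected and the offending records dropped in lax mode, or
fatal in strict mode — annotation batches routinely contain a few stray
records, and silently keeping them would corrupt downstream counts.

The eleven default entity categories shipped in `kg_schema()` are
configuration, not ground truth: annotation guidelines differ, so any
category vocabulary can be supplied (YAML via `read_schema()`).

### Synonym consolidation

`apply_consolidation()` rewrites every mention label through a curated
two-column synonym table. Matching is **exact on the lexically normalized
string** (case-folded, whitespace-collapsed, with a single trailing
parenthetical of at most 10 characters stripped, e.g. an abbreviation as in
"Mediterranean diet (MD)"); it is deliberately not fuzzy, because the
table is expert-curated and fuzzy matching would inject unreviewed merges.
The parenthetical limit avoids mangling chemical names that contain
parentheses. Two invariants are enforced at load time: no variant maps to
two normalized forms, and no normalized form is itself a variant of another
entry (no chains), which makes consolidation idempotent. A label whose
folded form equals a table normalized form is emitted in the table's
canonical casing; labels absent from the table pass through lexically
normalized. "Unified mentions" counts only table-driven merges — pure
case/whitespace canonicalization is not a merge.

### Edge aggregation

`aggregate_edges()` groups relation instances by the consolidated
(source, target, type) triple. Design choices that were genuinely open:

* **The edge key excludes polarity.** When merged instances disagree, the
  majority class wins and ties resolve to neutral; the conflict is flagged
  on the edge. One polarity per edge keeps the weighting well-defined, and
  neutral is the only defensible tie-break because it neither rewards nor
  penalises the edge.
* **$F$ counts unique documents**; the raw instance count is retained
  separately (`instance_count`) for provenance, so a document annotating
  the same triple twice raises instances but not $F$.
* **Self-loops are dropped** (with a warning): a relation whose endpoints
  consolidate to the same label carries no direction and no mechanism.
* **Direction is never symmetrized**, even for `associated_with`: the
  schema is directional and collapsing direction would destroy chain
  traversal.

Entities participating in no edge are pruned from the graph; the build log
records counts at every stage (mentions, entities before/after pruning,
instances, unique edges, conflicts).

### Topology

Degrees and hubs are computed on the **directed multigraph**: a node's
degree is its count of incident unique edges (in + out) and its weighted
degree the sum of their weights. Clustering and density, by contrast, are
classical undirected quantities, so they are computed on the **undirected
simple projection** in which parallel edges of different relation types
collapse into one link: density is observed links over $N(N-1)/2$, and the
mean local clustering coefficient averages over *all* nodes with
degree-below-2 nodes contributing 0 (some convention is required for the
mean to be well-defined; this one is stated in the report header).
Whether the clustering should be weighted is genuinely open; the unweighted
projection was chosen and is flagged in the report's `conventions` field.
Hub ties break lexicographically so reports are reproducible. Community
detection is deliberately out of scope.

### Pathway evidence

A mechanistic pathway is an ordered list of stages
(diet → microbiome → metabolite → outcome), each with a curated keyword
list. Keyword matching is **whole-word and case-insensitive** — free
substring matching would let "art" match "heart" — so "butyrate" matches
"butyrate production" but not "butyrogenesis". An edge supports a pathway
when both endpoints match some stage and its direction respects stage order
(same-stage edges allowed). The reported metrics are `docs`, the number of
unique documents pooled over matched edges, and `rels`, the number of
**relation instances** those edges aggregate — instances, not unique edges,
because a pathway's strength of support is how often it was asserted, and
this choice is recorded in the report metadata. Chain extraction
(`extract_chains()`) enumerates simple directed paths from a first-stage
match to a last-stage match with non-decreasing stages (skips allowed),
capped at 6 nodes by default to guard against combinatorial blow-up; chains
render with ↑/↓ arrows derived from edge polarity.

### Coverage benchmarking

External validation compares the graph against curated marker sets
(compiled in the style of KEGG/Reactome pathway definitions):

$$C_{entity} = M_{detected} / M_{total} \times 100\%,\qquad
  C_{edge} = R_{found} / R_{expected} \times 100\%.$$

Marker matching reuses the whole-word rule plus per-marker synonym lists,
because database labels ("butanoate") rarely match literature surface forms
("butyrate") verbatim. Expected edges are directional by default, with an
undirected option. Percentages are rounded **half-up to one decimal**, the
convention used when such tables are printed. The shipped
`markers_synthetic.json` is a synthetic, illustrative marker-set file — it
demonstrates the format and is not a curated reference.

## The synthetic-corpus generator

No annotated corpus ships with the package, so `generate_corpus()` creates
one with the statistical structure the analysis assumes, together with a
ground-truth manifest computed from the generator's own bookkeeping (exact
label equality and the closed-form weight), independently of the pipeline
code under test. It emulates:

* per-triple evidence frequencies across unique abstracts in the 1–9
  range, with background (distractor) edges drawn mostly as singletons
  from a truncated geometric distribution;
* a three-class polarity mix for background edges of
  62.6% neutral / 23.1% beneficial / 14.3% harmful;
* lexical variant fragmentation: planted variants of canonical labels that
  only the synonym table can reunite;
* isolated, relation-free mentions that pruning must remove;
* planted multi-step diet → microbiome → metabolite → outcome chains
  distributed across documents, each chain edge assigned its stated number
  of distinct documents sampled without replacement (plus optional
  within-document duplicates so `instance_count` can exceed $F$).

All randomness flows through one seed; the same spec yields byte-identical
files. The default spec (`default_synthetic_spec()`) uses 200 documents,
two planted chains with per-edge frequencies spanning 3–9, 1000 background
edges, three planted variants and 40 isolated mentions — sizes chosen so a
full generate-build-validate cycle runs in a few seconds while every
recovery check remains exact.

What the generator does **not** emulate: natural-language abstracts, real
lexical diversity (labels are clean tokens), annotator disagreement or
boundary noise, and the long-tailed document-length distribution of real
corpora. Green recovery tests therefore demonstrate that the pipeline's
bookkeeping is exact — that frequencies, weights, consolidation counts,
pathway metrics and coverages are computed correctly — not that the keyword
lists or synonym tables used on a real corpus are complete.

## Numerical choices

* Weights are exact doubles internally; reports round to 2–3 decimals.
* Percentage shares and coverages round half-up to one decimal.
* Hub and edge orderings are deterministic (descending measure, then
  lexicographic label), so every output file is byte-reproducible given
  identical inputs, configuration and seed.
* Degenerate inputs are defined rather than accidental: an empty corpus
  builds an empty graph; a pathway with no matching nodes reports zero
  evidence (not an error); density on fewer than two nodes is an error;
  a marker set must be non-empty.

## Limitations

The pipeline begins at annotations: it performs no retrieval, no NER/RE,
and no ontology alignment. Corpus-scale figures from any particular
annotation project (total entities, hub degrees, corpus-level clustering)
depend on that project's corpus and curation tables and are not
reproducible from this package alone; what the package guarantees is the
arithmetic and the bookkeeping connecting annotations to reported
quantities. Indexed same-type edge labels in reports (e.g. `affects_1`)
enumerate distinct source-target pairs ranked by weight, which matches
their stated semantics but cannot be checked against any external table.
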