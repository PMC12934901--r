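# Default annotation schema: 11 entity categories, 12 directional relation
# types with their default polarity classes, and the polarity multipliers
# used by the edge-weighting function W = ln(F+1) * P.
categories:
  - nutrition
  - microbiome
  - metabolite
  - gene
  - protein
  - physiological_process
  - clinical_outcome
  - disease
  - population
  - intervention
  - biomarker
relation_types:
  - associated_with
  - affects
  - causes
  - regulates
  - modifies
  - maintains
  - assists
  - benefits
  - increases
  - reduces
  - inhibits
  - harms
type_to_polarity:
  associated_with: neutral
  affects: neutral
  causes: neutral
  regulates: neutral
  modifies: neutral
  maintains: neutral
  assists: neutral
  benefits: beneficial
  increases: beneficial
  reduces: harmful
  inhibits: harmful
  harms: harmful
multipliers:
  beneficial: 1.2
  harmful: 1.1
  neutral: 1.0
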