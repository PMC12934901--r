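{
  "comment": "Hand-tallied expectations for the 12-document regression fixture; weights are ln(F+1) x P at full precision.",
  "totals": {"documents": 12, "mentions": 34, "relation_instances": 18},
  "consolidation": {"mentions_unified": 5, "normalized_forms": 3, "share_unified": 14.7},
  "nodes_after_pruning": 14,
  "entities_before_pruning": 16,
  "unique_edges": 9,
  "polarity_counts": {"beneficial": 5, "harmful": 2, "neutral": 2},
  "polarity_shares": {"beneficial": 55.6, "harmful": 22.2, "neutral": 22.2},
  "edges": [
    {"source": "fiber", "target": "Faecalibacterium prausnitzii", "relation_type": "increases", "polarity": "beneficial", "frequency": 3, "instance_count": 4, "weight": 1.6635532333438687, "docs": "d01;d02;d03"},
    {"source": "Faecalibacterium prausnitzii", "target": "butyrate", "relation_type": "increases", "polarity": "beneficial", "frequency": 2, "instance_count": 2, "weight": 1.3183347464017318, "docs": "d02;d03"},
    {"source": "butyrate", "target": "inflammation", "relation_type": "reduces", "polarity": "beneficial", "frequency": 2, "instance_count": 2, "weight": 1.3183347464017318, "docs": "d03;d04"},
    {"source": "high-fat diet", "target": "LPS", "relation_type": "increases", "polarity": "harmful", "frequency": 2, "instance_count": 2, "weight": 1.2084735175349208, "docs": "d05;d06"},
    {"source": "LPS", "target": "endotoxemia", "relation_type": "causes", "polarity": "neutral", "frequency": 1, "instance_count": 1, "weight": 0.6931471805599453, "docs": "d06"},
    {"source": "endotoxemia", "target": "insulin resistance", "relation_type": "increases", "polarity": "harmful", "frequency": 1, "instance_count": 1, "weight": 0.7624618986159398, "docs": "d07"},
    {"source": "polyphenols", "target": "Akkermansia muciniphila", "relation_type": "affects", "polarity": "neutral", "frequency": 2, "instance_count": 2, "weight": 1.0986122886681098, "docs": "d08;d09", "conflict": true},
    {"source": "Mediterranean diet", "target": "gut microbiota", "relation_type": "benefits", "polarity": "beneficial", "frequency": 2, "instance_count": 2, "weight": 1.3183347464017318, "docs": "d10;d11"},
    {"source": "short-chain fatty acids", "target": "immune regulation", "relation_type": "benefits", "polarity": "beneficial", "frequency": 2, "instance_count": 2, "weight": 1.3183347464017318, "docs": "d11;d12"}
  ],
  "pathways": [
    {"pathway_id": "fiber_axis", "docs": 4, "rels": 8, "matched_edges": 3, "n_chains": 1,
     "chain_nodes": ["fiber", "Faecalibacterium prausnitzii", "butyrate", "inflammation"]},
    {"pathway_id": "hfd_axis", "docs": 3, "rels": 4, "matched_edges": 3, "n_chains": 2,
     "chain_nodes": ["high-fat diet", "LPS", "endotoxemia", "insulin resistance"]}
  ],
  "top_weighted_hub": {"label": "Faecalibacterium prausnitzii", "weighted_degree": 2.9818879797456005, "degree": 2}
}
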