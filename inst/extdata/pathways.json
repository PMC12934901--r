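[
  {
    "pathway_id": "fiber_scfa_inflammation",
    "name": "Fiber-SCFA-Inflammation",
    "polarity_claim": "beneficial",
    "stages": {
      "diet": ["dietary fiber", "fiber", "inulin", "resistant starch"],
      "microbiome": ["Faecalibacterium", "Roseburia", "butyrate-producing"],
      "metabolite": ["butyrate", "short-chain fatty acids"],
      "outcome": ["intestinal barrier", "inflammation", "inflammatory"]
    }
  },
  {
    "pathway_id": "probiotic_scfa_immunity",
    "name": "Probiotic-SCFA-Immunity",
    "polarity_claim": "beneficial",
    "stages": {
      "diet": ["probiotic", "probiotics", "fermented food"],
      "microbiome": ["Lactobacillus", "Bifidobacterium"],
      "metabolite": ["short-chain fatty acids", "butyrate", "acetate", "propionate"],
      "outcome": ["immune regulation", "immunity", "immune function"]
    }
  },
  {
    "pathway_id": "hfd_lps_endotoxemia",
    "name": "High-Fat-LPS-Metabolic Dysfunction",
    "polarity_claim": "harmful",
    "stages": {
      "diet": ["high-fat diet", "high fat diet", "saturated fat"],
      "microbiome": ["dysbiosis"],
      "metabolite": ["LPS", "lipopolysaccharide"],
      "outcome": ["endotoxemia", "insulin resistance", "metabolic dysfunction"]
    }
  },
  {
    "pathway_id": "choline_tmao_cvd",
    "name": "Choline/Carnitine-TMAO-CVD",
    "polarity_claim": "harmful",
    "stages": {
      "diet": ["choline", "L-carnitine", "red meat"],
      "microbiome": ["Prevotella", "Clostridium", "gut microbiota"],
      "metabolite": ["TMA", "TMAO", "trimethylamine"],
      "outcome": ["atherosclerosis", "cardiovascular disease", "CVD"]
    }
  }
]
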