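[
  {
    "pathway_id": "butanoate_metabolism",
    "name": "Fiber Fermentation",
    "external_ref": "KEGG map00650 (synthetic marker set)",
    "markers": {
      "dietary fiber": ["fiber", "fermentable fiber"],
      "resistant starch": [],
      "inulin": [],
      "Faecalibacterium": ["Faecalibacterium prausnitzii"],
      "Roseburia": [],
      "Eubacterium": [],
      "butanoate": ["butyrate", "butyric acid"],
      "acetate": ["acetic acid"],
      "propionate": ["propionic acid"],
      "short-chain fatty acids": ["SCFA"],
      "intestinal barrier": ["gut barrier"],
      "colonocyte": [],
      "inflammation": ["inflammatory markers"],
      "histone deacetylase": ["HDAC"]
    },
    "expected_edges": [
      {"source": "dietary fiber", "target": "Faecalibacterium"},
      {"source": "dietary fiber", "target": "Roseburia"},
      {"source": "Faecalibacterium", "target": "butanoate"},
      {"source": "Roseburia", "target": "butanoate"},
      {"source": "butanoate", "target": "intestinal barrier"},
      {"source": "butanoate", "target": "inflammation"}
    ]
  },
  {
    "pathway_id": "secondary_bile_acids",
    "name": "Bile Acid Transformation",
    "external_ref": "KEGG map00121 (synthetic marker set)",
    "markers": {
      "dietary fat": ["fat", "high-fat diet"],
      "cholesterol": [],
      "primary bile acids": ["cholic acid", "chenodeoxycholic acid"],
      "Clostridium": [],
      "Bacteroides": [],
      "bile salt hydrolase": ["BSH"],
      "7-alpha-dehydroxylation": [],
      "deoxycholic acid": ["DCA"],
      "lithocholic acid": ["LCA"],
      "secondary bile acids": [],
      "FXR": ["farnesoid X receptor"],
      "TGR5": [],
      "lipid metabolism": []
    }
  },
  {
    "pathway_id": "tmao_signalling",
    "name": "TMAO signalling",
    "external_ref": "Reactome R-HSA-8964043 (synthetic marker set)",
    "markers": {
      "choline": [],
      "L-carnitine": ["carnitine"],
      "red meat": [],
      "phosphatidylcholine": ["lecithin"],
      "Prevotella": [],
      "Clostridium": [],
      "gut microbiota": [],
      "TMA": ["trimethylamine"],
      "TMAO": ["trimethylamine N-oxide"],
      "FMO3": ["flavin monooxygenase 3"],
      "foam cell": [],
      "atherosclerosis": [],
      "cardiovascular disease": ["CVD"]
    },
    "expected_edges": [
      {"source": "choline", "target": "gut microbiota"},
      {"source": "choline", "target": "TMA"},
      {"source": "L-carnitine", "target": "gut microbiota"},
      {"source": "L-carnitine", "target": "TMA"},
      {"source": "red meat", "target": "L-carnitine"},
      {"source": "red meat", "target": "gut microbiota"},
      {"source": "phosphatidylcholine", "target": "choline"},
      {"source": "Prevotella", "target": "TMA"},
      {"source": "Clostridium", "target": "TMA"},
      {"source": "gut microbiota", "target": "TMA"},
      {"source": "TMA", "target": "FMO3"},
      {"source": "TMA", "target": "TMAO"},
      {"source": "FMO3", "target": "TMAO"},
      {"source": "TMAO", "target": "foam cell"},
      {"source": "TMAO", "target": "atherosclerosis"},
      {"source": "TMAO", "target": "cardiovascular disease"},
      {"source": "foam cell", "target": "atherosclerosis"},
      {"source": "atherosclerosis", "target": "cardiovascular disease"},
      {"source": "gut microbiota", "target": "TMAO"}
    ]
  },
  {
    "pathway_id": "tlr_cascades",
    "name": "Inflammation/Immunity",
    "external_ref": "Reactome R-HSA-168898 (synthetic marker set)",
    "markers": {
      "LPS": ["lipopolysaccharide"],
      "dysbiosis": [],
      "TLR4": ["toll-like receptor 4"],
      "TLR2": [],
      "MyD88": [],
      "NF-kB": ["nuclear factor kappa B"],
      "TNF-alpha": ["tumor necrosis factor"],
      "IL-6": ["interleukin 6"],
      "IL-1beta": [],
      "cytokines": [],
      "inflammation": [],
      "intestinal permeability": ["leaky gut"],
      "endotoxemia": [],
      "insulin resistance": []
    }
  },
  {
    "pathway_id": "tryptophan_metabolism",
    "name": "Tryptophan Metabolism",
    "external_ref": "KEGG map00380 (synthetic marker set)",
    "markers": {
      "tryptophan": [],
      "gut microbiota": ["microbiota"],
      "indole": [],
      "indole-3-propionic acid": ["IPA"],
      "kynurenine": [],
      "serotonin": ["5-HT"],
      "melatonin": [],
      "aryl hydrocarbon receptor": ["AhR"],
      "gut-brain axis": [],
      "mood": [],
      "intestinal homeostasis": []
    }
  }
]
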