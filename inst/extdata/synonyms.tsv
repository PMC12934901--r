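normalized_label	variant_label
# curated example synonym table: variant -> normalized form
short-chain fatty acids	SCFA
short-chain fatty acids	SCFAs
gut microbiota	intestinal flora
gut microbiota	gut microbiome
gut microbiota	intestinal microbiota
Mediterranean diet	mediterranean
Mediterranean diet	alternate Mediterranean diet
Faecalibacterium prausnitzii	F. prausnitzii
LPS	lipopolysaccharide
trimethylamine N-oxide	TMAO
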