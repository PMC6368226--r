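probeset_id	gene_symbol
ps_DDR1_a	DDR1
ps_LTBP1_a	LTBP1
ps_LTBP1_b	LTBP1
ps_PDGFB_a	PDGFB
ps_SMURF1_a	SMURF1
ps_SNAI1_a	SNAI1
ps_TGFBR1_a	TGFBR1
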