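probeset_id	gene_symbol	direction	provenance
ps_ACTN1_a	ACTN1	1	algorithmic
ps_ACTN1_b	ACTN1	1	algorithmic
ps_ADGRF4_a	ADGRF4	1	algorithmic
ps_ADGRF4_b	ADGRF4	1	algorithmic
ps_AFAP1L2_a	AFAP1L2	1	algorithmic
ps_AFAP1L2_b	AFAP1L2	1	algorithmic
ps_ANKLE2_a	ANKLE2	1	algorithmic
ps_ANKLE2_b	ANKLE2	1	algorithmic
ps_ARHGEF18_a	ARHGEF18	1	algorithmic
ps_ARHGEF18_b	ARHGEF18	1	algorithmic
ps_ARHGEF40_a	ARHGEF40	1	algorithmic
ps_ARHGEF40_b	ARHGEF40	1	algorithmic
ps_BEAN1_a	BEAN1	1	algorithmic
ps_BEAN1_b	BEAN1	1	algorithmic
ps_BICDL1_a	BICDL1	-1	algorithmic
ps_BICDL1_b	BICDL1	-1	algorithmic
ps_BMP1_a	BMP1	1	algorithmic
ps_BMP1_b	BMP1	1	algorithmic
ps_CALD1_a	CALD1	1	algorithmic
ps_CALD1_b	CALD1	1	algorithmic
ps_CERCAM_a	CERCAM	1	algorithmic
ps_CERCAM_b	CERCAM	1	algorithmic
ps_CHST3_a	CHST3	1	algorithmic
ps_CHST3_b	CHST3	1	algorithmic
ps_CMTM3_a	CMTM3	1	algorithmic
ps_CMTM3_b	CMTM3	1	algorithmic
ps_COL1A1_a	COL1A1	1	algorithmic
ps_COL1A1_b	COL1A1	1	algorithmic
ps_COL7A1_a	COL7A1	1	algorithmic
ps_COL7A1_b	COL7A1	1	algorithmic
ps_DBN1_a	DBN1	1	algorithmic
ps_DBN1_b	DBN1	1	algorithmic
ps_DEPTOR_a	DEPTOR	-1	algorithmic
ps_DEPTOR_b	DEPTOR	-1	algorithmic
ps_EEPD1_a	EEPD1	1	algorithmic
ps_EEPD1_b	EEPD1	1	algorithmic
ps_EHF_a	EHF	-1	algorithmic
ps_EHF_b	EHF	-1	algorithmic
ps_EPB41L5_a	EPB41L5	-1	algorithmic
ps_EPB41L5_b	EPB41L5	-1	algorithmic
ps_EPHB2_a	EPHB2	1	algorithmic
ps_EPHB2_b	EPHB2	1	algorithmic
ps_EXOC6_a	EXOC6	-1	algorithmic
ps_EXOC6_b	EXOC6	-1	algorithmic
ps_FLNA_a	FLNA	1	algorithmic
ps_FLNA_b	FLNA	1	algorithmic
ps_FRMD6_a	FRMD6	1	algorithmic
ps_FRMD6_b	FRMD6	1	algorithmic
ps_GADD45B_a	GADD45B	1	algorithmic
ps_GADD45B_b	GADD45B	1	algorithmic
ps_GALNT2_a	GALNT2	1	algorithmic
ps_GALNT2_b	GALNT2	1	algorithmic
ps_IL11_a	IL11	1	algorithmic
ps_IL11_b	IL11	1	algorithmic
ps_ITGA5_a	ITGA5	1	algorithmic
ps_ITGA5_b	ITGA5	1	algorithmic
ps_JUNB_a	JUNB	1	algorithmic
ps_KCTD11_a	KCTD11	1	algorithmic
ps_KLF7_a	KLF7	1	algorithmic
ps_LAMC2_a	LAMC2	1	algorithmic
ps_LTBP1_a	LTBP1	1	curated
ps_LTBP3_a	LTBP3	1	algorithmic
ps_LTBP4_a	LTBP4	1	algorithmic
ps_MAF_a	MAF	1	algorithmic
ps_MAPRE2_a	MAPRE2	-1	algorithmic
ps_MBOAT2_a	MBOAT2	1	algorithmic
ps_METRNL_a	METRNL	1	algorithmic
ps_MLXIP_a	MLXIP	1	algorithmic
ps_MUC5AC_a	MUC5AC	-1	algorithmic
ps_MUC5B_a	MUC5B	-1	algorithmic
ps_NAV1_a	NAV1	1	algorithmic
ps_NCOR2_a	NCOR2	1	algorithmic
ps_NKAIN4_a	NKAIN4	1	algorithmic
ps_PDLIM7_a	PDLIM7	1	algorithmic
ps_PEA15_a	PEA15	1	algorithmic
ps_PIK3CD_a	PIK3CD	1	algorithmic
ps_PLAUR_a	PLAUR	1	algorithmic
ps_PLEK2_a	PLEK2	1	algorithmic
ps_PMEPA1_a	PMEPA1	1	algorithmic
ps_PPP1R13L_a	PPP1R13L	1	algorithmic
ps_PPP1R18_a	PPP1R18	1	algorithmic
ps_PTRF_a	PTRF	1	algorithmic
ps_PXDC1_a	PXDC1	1	algorithmic
ps_PXN_AS1_a	PXN-AS1	-1	algorithmic
ps_RHOD_a	RHOD	1	algorithmic
ps_SAMD4A_a	SAMD4A	1	algorithmic
ps_SERPINE1_a	SERPINE1	1	algorithmic
ps_SHANK3_a	SHANK3	1	algorithmic
ps_SKIL_a	SKIL	1	algorithmic
ps_SMAD7_a	SMAD7	1	algorithmic
ps_SNAI1_a	SNAI1	1	curated
ps_TBC1D30_a	TBC1D30	-1	algorithmic
ps_TGFB1I1_a	TGFB1I1	1	algorithmic
ps_TGFBR1_a	TGFBR1	1	curated
ps_THRB_a	THRB	-1	algorithmic
ps_TIMP2_a	TIMP2	1	algorithmic
ps_TMC5_a	TMC5	-1	algorithmic
ps_TP53I3_a	TP53I3	1	algorithmic
ps_TPM1_a	TPM1	1	algorithmic
ps_TRIO_a	TRIO	1	algorithmic
ps_TRMT10A_a	TRMT10A	-1	algorithmic
ps_TSPAN2_a	TSPAN2	1	algorithmic
ps_VCAN_a	VCAN	1	algorithmic
ps_WNT7A_a	WNT7A	1	algorithmic
ps_ZFP36L1_a	ZFP36L1	1	algorithmic
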