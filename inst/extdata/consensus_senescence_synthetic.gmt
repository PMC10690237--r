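consensus_senescence_synthetic	constructed 39-gene senescence signature (synthetic stand-in, not a published supplementary list)	CDKN1A	CDKN2A	CDKN2B	CDKN1B	TP53	SERPINE1	GLB1	IGFBP3	IGFBP7	GDF15	IL6	IL1A	IL1B	CXCL8	CXCL1	CXCL2	CCL2	CCL20	MMP1	MMP3	MMP12	TIMP1	ICAM1	TNF	TGFB1	NFKB1	STAT1	B2M	TNFRSF10C	IGFBP5	LMNB1	MKI67	CCNA2	CCNB1	CDK1	FOXM1	E2F1	TOP2A	HMGB2
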