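gene	direction
CDKN1A	induce
CDKN2A	induce
CDKN2B	induce
CDKN1B	induce
TP53	induce
SERPINE1	induce
GLB1	induce
IGFBP3	induce
IGFBP7	induce
GDF15	induce
IL6	induce
IL1A	induce
IL1B	induce
CXCL8	induce
CXCL1	induce
CXCL2	induce
CCL2	induce
CCL20	induce
MMP1	induce
MMP3	induce
MMP12	induce
TIMP1	induce
ICAM1	induce
TNF	induce
TGFB1	induce
NFKB1	induce
STAT1	induce
B2M	induce
TNFRSF10C	induce
IGFBP5	induce
LMNB1	inhibit
MKI67	inhibit
CCNA2	inhibit
CCNB1	inhibit
CDK1	inhibit
FOXM1	inhibit
E2F1	inhibit
TOP2A	inhibit
HMGB2	inhibit
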