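druggable_targets	curated immunomodulatory and druggable cancer targets	TGFB1	SMAD3	IL10	VEGFA	VTCN1	SIGLEC15	CEACAM1	LGALS9	HAVCR2	ADORA2A	ENTPD1	NT5E	PRMT1	PKM	SLC2A1	CXCL9	CXCL10	CXCL11	CCL4	CCL5	CD27	CD40	CD80	CD86	ICOS	TNFRSF9	IL2RA	CD274	PDCD1	CTLA4	LAG3	TIGIT	EGFR	ERBB2	MET	ALK	KRAS	BRAF	PIK3CA	AKT1	MTOR	CDK4	CDK6	CDK7	AURKA	PLK1	WEE1	PARP1	IDO1	ARG1	CSF1R	AXL	MERTK	TNFRSF4	KDR	FGFR1	FGFR2	JAK1	JAK2	STAT3
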