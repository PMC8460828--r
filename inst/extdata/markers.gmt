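T_cells	T_cells	CD3D	CD3E	CD3G	CD5	CD6	TRAC
CD8_T_cells	CD8_T_cells	CD8A	CD8B	GZMK
Cytotoxic_lymphocytes	Cytotoxic_lymphocytes	GZMA	GZMB	PRF1	KLRD1	NKG7	GNLY
B_lineage	B_lineage	CD19	MS4A1	CD79A	CD79B	PAX5	IGKC
NK_cells	NK_cells	NCR1	KIR2DL3	KLRC1	XCL1	EOMES
Monocytic_lineage	Monocytic_lineage	CD14	CD163	CSF1R	ITGAM	FCGR2A
Myeloid_dendritic_cells	Myeloid_dendritic_cells	CD1C	FLT3	CLEC10A	FCER1A
Neutrophils	Neutrophils	FCGR3B	CSF3R	S100A8	S100A9	CEACAM3
Endothelial_cells	Endothelial_cells	PECAM1	VWF	CDH5	CLDN5	KDR
Fibroblasts	Fibroblasts	COL1A1	COL3A1	DCN	FAP	PDGFRB
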