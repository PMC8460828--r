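interferon_gamma_response	IFN-gamma response	STAT1	IRF1	GBP1	CXCL9	CXCL10	CXCL11	IDO1	HLA_DRA
antigen_presentation	MHC class I antigen processing	HLA_A	HLA_B	HLA_C	B2M	TAP1	TAP2	PSMB9
t_cell_activation	T cell receptor activation	CD3D	CD3E	CD28	LCK	ZAP70	IL2RA	ICOS
tgf_beta_signaling	TGF-beta signaling	TGFB1	TGFBR1	TGFBR2	SMAD3	SMAD7	SERPINE1
cytokine_chemokine_signaling	cytokine and chemokine signaling	CCL4	CCL5	CXCL13	IL6	IL10	CCR5	CXCR3
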