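immuno_stimulatory	trafficking and activation genes, depressed with 9p21 loss	CXCL9	CXCL10	CXCL11	CCL4	CCL5	CD27	CD40	CD80	CD86	ICOS	TNFRSF9	IL2RA	CD274	PDCD1
immuno_suppressive	suppressive signaling genes, elevated with 9p21 loss	TGFB1	SMAD3	IL10	VEGFA	VTCN1	SIGLEC15	CEACAM1	LGALS9	HAVCR2	ADORA2A	ENTPD1	NT5E	PRMT1	PKM
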