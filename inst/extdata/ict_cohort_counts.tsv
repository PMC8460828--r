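cohort	stratum_a	responders_a	total_a	stratum_b	responders_b	total_b	test
solid_responsive	WT	8	30	LOSS	1	25	fisher_2x2
resectable_melanoma	hi_hi	3	4	lo_lo	0	5	fisher_2x2
melanoma_liu	hi_hi	11	18	lo_lo	4	14	fisher_2x2
melanoma_gide	hi_hi	9	13	lo_lo	4	13	fisher_2x2
melanoma_riaz	hi_hi	4	10	lo_lo	1	9	fisher_2x2
melanoma_combined	hi_hi	27	45	lo_lo	9	41	fisher_2x2
nsclc_dcb	WT	40	137	LOSS	1	14	lr_chisq
muc_imvigor	hi_hi	40	124	lo_lo	15	127	fisher_2x2
pooled	WT_or_hi_hi	132	394	LOSS_or_lo_lo	28	229	fisher_2x2
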