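sample_id	gene_id	truncating	homozygous
Me01	BRAF	FALSE	FALSE
Me01	HYDIN	FALSE	FALSE
Me01	SPTA1	FALSE	FALSE
Me01	XKR6	TRUE	FALSE
Me02	NRAS	FALSE	TRUE
Me02	SMC1B	FALSE	FALSE
Me04	BRAF	FALSE	TRUE
Me04	MADD	FALSE	FALSE
Me04	SPTA1	FALSE	FALSE
Me05	MKS1	FALSE	FALSE
Me08	BRAF	FALSE	FALSE
Me08	PKHD1	FALSE	FALSE
Me12	BRAF	FALSE	FALSE
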