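sample_id	gene_id	homozygous_deletion
Me01	CDKN2A	TRUE
Me02	CDKN2A	TRUE
Me02	MAP2K4	FALSE
Me05	AXIN1	FALSE
Me05	CDKN2A	FALSE
Me05	JAK2	FALSE
Me05	KIT	FALSE
Me05	PDGFRA	FALSE
Me05	RB1	FALSE
Me05	TET2	FALSE
Me05	ZRANB1	FALSE
Me08	APC	FALSE
Me08	MAP2K4	FALSE
Me12	CDKN2A	TRUE
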