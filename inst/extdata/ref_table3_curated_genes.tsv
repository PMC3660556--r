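class	sample_id	gene_id	truncating	double_mutated	homozygous	compound_loss
PI3K/Akt signalling	Me01	PIK3R4	FALSE	FALSE	FALSE	FALSE
PI3K/Akt signalling	Me02	PIK3C2G	TRUE	TRUE	FALSE	FALSE
PI3K/Akt signalling	Me04	PIK3C2G	FALSE	FALSE	FALSE	FALSE
PI3K/Akt signalling	Me04	PREX2	FALSE	TRUE	FALSE	FALSE
PI3K/Akt signalling	Me08	PIK3CG	FALSE	FALSE	FALSE	FALSE
PI3K/Akt signalling	Me08	PREX2	FALSE	TRUE	FALSE	FALSE
MAPK signalling	Me01	MAP3K4	FALSE	FALSE	FALSE	FALSE
MAPK signalling	Me01	BRAF	FALSE	FALSE	FALSE	FALSE
MAPK signalling	Me04	BRAF	FALSE	FALSE	TRUE	FALSE
MAPK signalling	Me05	MAPK6	FALSE	FALSE	FALSE	FALSE
MAPK signalling	Me08	MAP2K3	FALSE	FALSE	FALSE	FALSE
MAPK signalling	Me08	BRAF	FALSE	FALSE	FALSE	FALSE
MAPK signalling	Me12	MAP3K5	FALSE	FALSE	FALSE	FALSE
MAPK signalling	Me12	BRAF	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me01	GRIN2B	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me01	GRIN3A	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me01	GRM5	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me01	PLCB1	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me01	PLCB4	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me01	PLCE1	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me01	PLCZ1	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me02	GRIN3A	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me04	GRM1	FALSE	FALSE	FALSE	FALSE
Glutamate signalling	Me04	PLCXD2	FALSE	FALSE	FALSE	FALSE
RAS-RAF Ser/Thr kinases	Me01	BRAF	FALSE	FALSE	FALSE	FALSE
RAS-RAF Ser/Thr kinases	Me02	NRAS	FALSE	FALSE	TRUE	FALSE
RAS-RAF Ser/Thr kinases	Me04	BRAF	FALSE	FALSE	TRUE	FALSE
RAS-RAF Ser/Thr kinases	Me08	BRAF	FALSE	FALSE	FALSE	FALSE
RAS-RAF Ser/Thr kinases	Me12	BRAF	FALSE	FALSE	FALSE	FALSE
Protein tyrosine kinases	Me01	FGFR1	FALSE	FALSE	FALSE	FALSE
Protein tyrosine kinases	Me02	MET	FALSE	FALSE	FALSE	FALSE
Protein tyrosine kinases	Me04	PTK2B	FALSE	FALSE	FALSE	FALSE
Protein tyrosine kinases	Me05	PTK7	FALSE	FALSE	FALSE	FALSE
Metalloproteinases	Me01	ADAM22	FALSE	FALSE	FALSE	TRUE
Metalloproteinases	Me01	ADAMTS18	FALSE	FALSE	FALSE	FALSE
Metalloproteinases	Me01	MMP24	FALSE	FALSE	FALSE	FALSE
Metalloproteinases	Me01	MMP25	FALSE	FALSE	FALSE	FALSE
Metalloproteinases	Me02	ADAMTS9	FALSE	FALSE	FALSE	FALSE
Metalloproteinases	Me04	ADAMTS12	TRUE	FALSE	FALSE	FALSE
Metalloproteinases	Me08	ADAM23	FALSE	FALSE	FALSE	FALSE
Metalloproteinases	Me08	ADAMTS6	FALSE	FALSE	FALSE	FALSE
Metalloproteinases	Me08	ADAMTS9	FALSE	FALSE	FALSE	FALSE
Metalloproteinases	Me08	MMP19	FALSE	FALSE	FALSE	FALSE
Protein tyrosine phosphatases	Me01	PTPN1	FALSE	FALSE	FALSE	FALSE
Protein tyrosine phosphatases	Me01	PTPRK	FALSE	FALSE	FALSE	FALSE
Protein tyrosine phosphatases	Me02	PTPN13	FALSE	FALSE	FALSE	FALSE
Protein tyrosine phosphatases	Me04	PTPN13	FALSE	FALSE	FALSE	FALSE
Protein tyrosine phosphatases	Me04	PTPRF	FALSE	FALSE	TRUE	FALSE
Protein tyrosine phosphatases	Me05	PTPRD	FALSE	FALSE	FALSE	TRUE
Protein tyrosine phosphatases	Me12	PTPLA	FALSE	FALSE	TRUE	FALSE
G protein-coupled receptors	Me01	GPR64	FALSE	FALSE	FALSE	FALSE
G protein-coupled receptors	Me01	GPR101	FALSE	FALSE	TRUE	FALSE
G protein-coupled receptors	Me01	GPR112	FALSE	FALSE	TRUE	FALSE
G protein-coupled receptors	Me01	GPR158	FALSE	FALSE	FALSE	FALSE
G protein-coupled receptors	Me01	GRM5	FALSE	FALSE	FALSE	FALSE
G protein-coupled receptors	Me02	GPR113	FALSE	FALSE	TRUE	FALSE
G protein-coupled receptors	Me04	GPR151	TRUE	FALSE	TRUE	FALSE
G protein-coupled receptors	Me04	GRM1	FALSE	FALSE	FALSE	FALSE
G protein-coupled receptors	Me05	GPR112	FALSE	FALSE	TRUE	FALSE
G protein-coupled receptors	Me05	GPR113	FALSE	FALSE	FALSE	FALSE
G protein-coupled receptors	Me05	GPR133	FALSE	FALSE	FALSE	FALSE
G protein-coupled receptors	Me08	GPR158	FALSE	FALSE	FALSE	FALSE
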