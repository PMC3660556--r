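gene_id	n_samples	samples	n_ns
C4orf23	2	Me04,Me05	2
PAICS	2	Me01,Me02	2
CNST	2	Me01,Me12	2
KIF23	2	Me01,Me08	2
MRPL1	2	Me01,Me08	2
MUC19	2	Me01,Me08	2
DCAKD	2	Me01,Me04	2
MRPL53	2	Me01,Me04	2
RBMXL1	2	Me01,Me04	4
ZNF66P	3	Me01,Me04,Me05	3
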