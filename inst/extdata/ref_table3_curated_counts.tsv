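class	n_ns	n_s
PI3K/Akt signalling	10	1
MAPK signalling	8	3
Glutamate signalling	10	13
RAS-RAF Ser/Thr kinases	5	0
Protein tyrosine kinases	4	2
Metalloproteinases	10	7
Protein tyrosine phosphatases	7	3
G protein-coupled receptors	12	5
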