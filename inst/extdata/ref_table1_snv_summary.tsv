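sample_id	n_total	n_novel	n_novel_coding	n_hq	n_ns	n_s	ns_s
Me01	128827	11126	2791	992	659	333	1.98
Me02	131830	8360	1626	563	385	178	2.16
Me04	159708	10230	1733	598	370	228	1.62
Me05	128087	6001	1117	283	189	94	2.01
Me08	161058	9534	1697	563	369	194	1.90
Me12	161721	7869	1224	326	200	126	1.59
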