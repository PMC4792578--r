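gene_a_id	gene_a_symbol	gene_b_id	gene_b_symbol
1843	DUSP1	983	CDK1
8440	NCK2	983	CDK1
2908	NR3C1	58	ACTA1
2625	GATA3	581	BAX
1845	DUSP3	7204	TRIO
8878	SQSTM1	835	CASP2
8660	IRS2	5153	PDE1B
6196	RPS6KA2	30849	PIK3R4
1997	ELF1	983	CDK1
9146	HGS	983	CDK1
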