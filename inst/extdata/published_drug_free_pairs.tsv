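gene_a_id	gene_a_symbol	gene_b_id	gene_b_symbol
55182	RNF220	27338	UBE2S
6124	RPL4	3315	HSPB1
7327	UBE2G2	51588	PIAS4
22794	CASC3	23658	LSM5
6205	RPS11	9861	PSMD6
896	CCND3	983	CDK1
5689	PSMB1	27338	UBE2S
1021	CDK6	990	CDC6
5707	PSMD1	27338	UBE2S
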