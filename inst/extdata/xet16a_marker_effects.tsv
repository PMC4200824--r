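trait	snp	two_a	d	d_over_a	two_a_over_sp	freq	allele	a_add
lignin	SNP6	1.333	2.43	3.646	0.531	0.482	C	-1.412
lignin	SNP16	22.019	9.7645	0.887	8.353	0.461	C	3.524
lignin	SNP29	5.909	-2.8905	-0.978	2.241	0.335	G	1.964
dbh	SNP15	0.994	-0.211	-0.425	0.177	0.485	T	-0.164
volume	SNP15	0.029	-0.0255	-1.759	0.075	0.485	T	0.003
fiber_length	SNP21	0.0214	0.0153	1.43	0.255	0.495	T	-0.012
fiber_length	SNP22	0.087	-0.0225	-0.517	1.036	0.494	G	0.032
fiber_length	SNP23	0.013	-0.002	-0.308	0.163	0.460	C	-0.003
fiber_length	SNP29	0.152	0.081	1.066	1.81	0.335	G	-0.051
fiber_width	SNP27	2.189	2.2155	2.024	1.104	0.496	A	-1.624
mfa	SNP14	3.703	-1.5205	-0.821	0.818	0.479	T	-0.385
mfa	SNP21	1.414	-1.661	-2.349	0.313	0.495	T	0.340
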