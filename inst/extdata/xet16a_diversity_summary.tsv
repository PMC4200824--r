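region	L_eff	S	pi	theta_w
five_prime_utr	146	5	0.01350	0.00792
exon1	190	12	0.01226	0.01460
exon1_synonymous	45.10	3	0.01290	0.01537
exon1_nonsynonymous	143.9	9	0.01216	0.01446
intron1	163	14	0.02461	0.01985
exon2	101	4	0.00947	0.00915
exon2_synonymous	23.00	4	0.04160	0.04019
exon2_nonsynonymous	76.00	0	0.00000	0.00000
intron2	173	1	0.00239	0.00142
exon3	182	2	0.00433	0.00254
exon3_synonymous	38.28	1	0.00885	0.00604
exon3_nonsynonymous	141.72	1	0.00317	0.00163
intron3	789	61	0.01746	0.01851
exon4	400	25	0.00548	0.01445
exon4_synonymous	83.60	10	0.01682	0.02765
exon4_nonsynonymous	312.40	15	0.00252	0.01110
three_prime_utr	122	10	0.01810	0.01894
Total	2266	134	0.01266	0.01392
Total_synonymous	190.98	18	0.01719	0.02178
Total_nonsynonymous	679.02	25	0.00439	0.00851
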