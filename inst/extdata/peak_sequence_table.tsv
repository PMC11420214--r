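name	sequence	pct_within_cluster	pct_peak_overall	pct_cluster_overall
CS1	GACAGCCGAGAAAUGAGUGGCCUAAAUGGGAGAAUGAGCU	65.41	23.68	36.21
CS2	GACUGCGCGUAUGAGUGGCGGCUAAAGAGGAGAAUGAGCG	81.61	20.59	25.23
CS3	ACGGGUGGGUAAUCUAGUGUCCGCGGAAUAGAACGAAACA	49.97	15.55	31.12
CS4	GGAUGGUGCGAACUGAGUGGGCUAAUUAGGAGAAUGAGCG	30.93	0.23	0.73
CS5	GGAGGGUGACAUCGUUGAGAGAGAAUGGGGAUAUUGAACU	13.40	0.12	0.88
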