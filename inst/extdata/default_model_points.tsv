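mutation_rate	N_star	optimal_mismatch_rate	unique_rate
0.01	6	6	1
0.02	9	9	1
0.03	11	11	1
0.04	12	12	1
0.05	15	15	1
0.060000000000000005	17	17	1
0.06999999999999999	18	18	1
0.08	20	20	1
0.09	22	22	1
0.09999999999999999	23	23	1
0.11	25	25	1
0.12	27	27	1
0.13	28	28	1
0.14	29	29	1
0.15	29	29	0.9999
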