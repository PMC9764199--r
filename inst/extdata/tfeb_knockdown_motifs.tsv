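motif	p_value	q_value_benjamini	n_sequences_with_motif	fg_pct	bg_pct	enrichment_ratio
NFY(CCAAT)	0.00	0.0287	198	28.78	22.40	1.284821429
BATF(bZIP)	0.00	0.0695	49	7.12	4.28	1.663551402
Hoxc9(Homeobox)	0.01	0.1218	35	5.09	2.97	1.713804714
Atf3(bZIP)	0.01	0.1218	48	6.98	4.48	1.558035714
AP-1(bZIP)	0.01	0.1331	52	7.56	5.01	1.508982036
Fra1(bZIP)	0.01	0.1331	42	6.10	3.88	1.572164948
Fos(bZIP)	0.01	0.1331	43	6.25	4.00	1.5625
Bach1(bZIP)	0.01	0.1331	8	1.16	0.36	3.222222222
c-Myc(bHLH)	0.01	0.1331	65	9.45	6.75	1.4
Bach2(bZIP)	0.01	0.1331	20	2.91	1.52	1.914473684
E2F7(E2F)	0.10	0.1668	67	9.74	7.35	1.325170068
Tcfcp2l1(CP2)	0.10	0.1668	24	3.49	2.10	1.661904762
NFE2L2(bZIP)	0.10	0.1976	6	0.87	0.29	3
Nrf2(bZIP)	0.10	0.2079	6	0.87	0.30	2.9
p53(p53)	0.10	0.2079	4	0.58	0.15	3.866666667
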