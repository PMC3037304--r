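species	n_loci	ssr_per_est_pct	avg_motif_length_bp	n_seq_with_ssr	seq_with_ssr_pct	n_seq_multi_ssr	multi_ssr_pct	n_single	n_compound
Chlamydomonas reinhardtii	980	2.41	33.21	886	2.19	94	9.78	899	81
Mesostigma viride	81	1.26	34.12	73	1.14	8	9.87	73	8
Marchantia polymorpha	437	4.33	22.56	436	4.32	1	0.52	425	12
Syntrichia ruralis	190	2.67	23.84	149	2.09	41	10.09	189	1
Physcomitrella patens	2753	3.46	24.20	2577	3.24	176	6.60	2670	83
Selaginella spp.	968	4.66	23.71	868	4.38	100	11.13	927	41
Adiantum capillus-veneris	749	4.64	31.14	599	3.71	150	20.86	624	125
Gnetum gnemon	212	3.48	23.62	195	3.21	17	8.45	203	9
Pinus taeda	568	0.97	30.89	530	0.91	38	6.85	539	29
Oryza sativa	4347	3.57	23.44	3934	3.23	413	10.19	4199	148
Arabidopsis thaliana	1890	0.84	26.52	1822	0.81	68	3.62	1837	53
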