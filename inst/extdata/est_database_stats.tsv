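species	n_sequences	total_bp	avg_bp_per_est	gc_percent
Chlamydomonas reinhardtii	40525	31388333	775	57.22
Mesostigma viride	6401	4273634	668	51.36
Marchantia polymorpha	10086	7836025	777	54.75
Syntrichia ruralis	7114	4764692	670	49.20
Physcomitrella patens	79537	58636814	737	47.60
Selaginella spp.	19830	18318250	924	51.38
Adiantum capillus-veneris	16138	9363530	580	45.97
Gnetum gnemon	6076	3420021	563	44.33
Pinus taeda	58522	44467932	760	43.64
Oryza sativa	121635	91859132	755	47.52
Arabidopsis thaliana	224496	72013660	321	41.10
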