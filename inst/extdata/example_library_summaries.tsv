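set_name	N	M	N_sing	auc	f50	median_maccs	property_distance
MEGx	935	2500	642	0.781	0.072	0.475	2.95
NATx	799	2500	400	0.768	0.116	0.444	1.07
GRAS	238	2249	150	0.926	0.004	0.375	1.00
GRAS subset	237	1195	150	0.867	0.021	0.38	NA
Carcinogenic	262	738	195	0.800	0.031	0.229	2.22
Carcinogenic subset	261	544	195	0.737	0.107	0.269	NA
Anticancer drugs	70	76	65	0.537	0.457	0.468	2.90
Non-anticancer drugs	844	1399	686	0.699	0.157	0.370	2.50
Clinical	603	713	565	0.576	0.409	0.438	2.62
Epigenetic focused	727	850	666	0.569	0.415	0.430	2.10
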