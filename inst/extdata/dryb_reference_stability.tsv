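# Published per-method stability values for ten candidate RT-qPCR reference
# genes of the leaf beetle Diorhabda rybakowi under two conditions (tissue,
# sex). delta_ct: mean pairwise SD in cycles; genorm: M value; normfinder:
# stability value; bestkeeper: SD (mean absolute deviation, cycles).
# Row order within each condition is the published table order and is the
# canonical tie-break order for ordinal ranking.
condition	gene	delta_ct	genorm	normfinder	bestkeeper
tissue	ACT	2.600	1.455	2.457	2.140
tissue	TUB	1.320	0.827	0.755	1.074
tissue	RPS18	1.030	0.394	0.125	0.388
tissue	GST	1.600	0.685	1.347	0.422
tissue	SYN6	1.090	0.527	0.047	0.732
tissue	GAPDH	1.440	0.947	0.834	0.879
tissue	EF1a	2.040	1.168	1.816	1.783
tissue	RPL13a	1.120	0.285	0.659	0.163
tissue	RPL19	1.130	0.356	0.583	0.381
tissue	RPS15	1.200	0.285	0.815	0.412
sex	ACT	0.560	0.331	0.249	0.926
sex	TUB	0.790	0.623	0.710	1.696
sex	RPS18	0.610	0.199	0.445	0.797
sex	GST	0.650	0.199	0.495	0.849
sex	SYN6	0.880	0.674	0.802	1.670
sex	GAPDH	0.840	0.403	0.775	0.539
sex	EF1a	0.620	0.489	0.346	1.376
sex	RPL13a	0.680	0.557	0.507	1.540
sex	RPL19	0.540	0.279	0.169	1.079
sex	RPS15	0.570	0.308	0.322	0.905
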