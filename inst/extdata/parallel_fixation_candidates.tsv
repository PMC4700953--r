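chrom	start	end	af_wl	af_bl	af_br	locus
1	46162081	46327076	0.90	0.87	0.86	gene_desert
1	117000428	117030951	0.98	0.86	0.91	gene_desert
1	149367651	149494049	0.95	0.88	0.95	LOC101748868
2	81956167	82594173	0.99	0.89	0.90	VSTM2A
2	94091060	94204500	0.92	0.97	0.96	CCDC102B
2	146767959	146879733	0.93	0.91	0.97	TSNARE1
3	50672559	50816899	0.97	0.95	0.91	C7ORF10
3	84015975	84072368	0.89	0.87	0.86	gene_desert
5	31562907	31623166	0.90	0.98	0.91	GJD2
5	40044067	40104591	0.95	0.91	0.89	TSHR
8	9411058	9463004	0.86	0.88	0.87	gene_desert
9	11798419	11901393	0.98	0.98	0.86	AGTR1
10	5316513	5444763	0.95	0.99	0.90	APBA2
11	35837	98851	0.98	0.98	0.85	LTB4R
24	6113460	6173359	0.88	0.97	0.90	BCDO2
28	579151	594628	0.94	0.90	0.86	SPPL2B
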