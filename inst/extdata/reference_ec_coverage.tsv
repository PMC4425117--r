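organism	total_cds	ec_cds_original	printed_pct_original	ec_cds_updated	multi_flagged	printed_actual_ec	printed_pct_updated	printed_pct_increase
Akkermansia muciniphila	2138	286	13.38	401	34	367	17.17	28.32
Alistipes putredinis	659	92	13.96	110	6	104	15.78	13.04
Alistipes shahii	2563	548	21.38	603	17	586	22.86	6.93
Bacillus subtilis	4140	912	22.03	941	8	933	22.54	2.30
Bacteroides fragilis	4406	366	8.31	377	5	372	8.443	1.64
Bifidobacterium longum	1903	68	3.57	672	189	483	25.38	610.29
Clostridium difficile	3902	1015	26.01	1035	6	1029	26.37	1.38
Clostridium leptum	602	100	16.61	114	4	110	18.27	10.00
Clostridium perfringens	2878	504	17.51	539	10	529	18.38	4.96
Desulfovibrio desulfuricans	2356	292	12.39	392	32	360	15.28	23.29
Escherichia coli	4967	612	12.32	1542	285	1257	25.31	105.39
Eubacterium rectale	2898	636	21.95	696	16	680	23.46	6.92
Faecalibacterium prausnitzii	2756	586	21.26	641	17	624	22.64	6.48
Lactobacillus acidophilus	1876	486	25.91	585	31	554	29.53	13.99
Methanobrevibacter smithii	1795	414	23.06	454	12	442	24.62	6.76
Odoribacter splanchnicus	3498	515	14.72	603	27	576	16.47	11.84
Prevotella ruminicola	2791	480	17.20	519	12	507	18.17	5.62
Roseburia intestinalis	3630	709	19.53	793	17	776	21.38	9.45
Ruminococcus bromii	1811	467	25.79	496	9	487	26.89	4.28
Weissella koreensis	1335	93	6.97	288	61	227	17	144.09
Bacteroides caccae	3441	0	0.00	76	19	57	1.656
Bacteroides thetaiotaomicron	4787	0	0.00	413	125	288	6.016
Bacteroides vulgatus	4065	0	0.00	267	80	187	4.6
Clostridium bolteae	5830	0	0.00	737	227	510	8.748
Sutterella wadsworthensis	2433	0	0.00	136	39	97	3.987
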