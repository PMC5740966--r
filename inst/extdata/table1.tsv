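patient	tissue	total	exon_antisense_count	exon_antisense_pct	exon_sense_count	exon_sense_pct	intron_antisense_count	intron_antisense_pct	intron_sense_count	intron_sense_pct	miRNA_count	miRNA_pct	rRNA_count	rRNA_pct	repeat_count	repeat_pct	scRNA_count	scRNA_pct	snRNA_count	snRNA_pct	snoRNA_count	snoRNA_pct	tRNA_count	tRNA_pct	unannotated_count	unannotated_pct
Q1	N	28277250	2403	0.01	179469	0.63	6658	0.02	19589	0.07	21189795	74.94	1066129	3.77	18421	0.07	20980	0.07	29803	0.11	57285	0.20	326441	1.15	5360132	18.96
Q1	T	27918838	3281	0.01	189423	0.68	9349	0.03	21878	0.08	19224820	68.86	1327029	4.75	23952	0.09	88860	0.32	82114	0.29	203246	0.73	1064063	3.81	5680444	20.35
Q2	N	35391692	3470	0.01	298030	0.84	26105	0.07	80756	0.23	15998067	45.2	5369926	15.17	76891	0.22	196764	0.56	199951	0.56	221878	0.63	8445871	23.86	4472358	12.64
Q2	T	33773903	10013	0.03	524796	1.55	25779	0.08	164968	0.49	18912932	56.00	4493690	13.31	158765	0.47	106115	0.31	855596	2.53	690244	2.04	767289	2.27	7062748	20.91
Q3	N	35735732	1705	0.00	297385	0.83	4644	0.01	24114	0.07	23955712	67.04	1974819	5.53	35437	0.10	151635	0.42	71211	0.20	131070	0.37	1937351	5.42	7150228	20.01
Q3	T	36095235	4090	0.01	497973	1.38	8652	0.02	82083	0.23	19275478	53.40	3251981	9.01	104960	0.29	189016	0.52	281679	0.78	516959	1.43	5106698	14.15	6774339	18.77
Q4	N	45235749	2750	0.01	68350	0.15	5387	0.01	14524	0.03	34012084	75.19	1382848	3.06	29433	0.07	71732	0.16	30671	0.07	71326	0.16	982107	2.17	8564307	18.93
Q4	T	32598915	2939	0.01	52485	0.16	8446	0.03	18961	0.06	24364229	74.74	690166	2.12	45388	0.14	43589	0.13	32698	0.10	106106	0.33	484692	1.49	6749107	20.70
Q5	N	34197138	15613	0.05	1110918	3.25	4628	0.01	19319	0.06	22754694	66.54	1418810	4.15	25247	0.07	31011	0.09	32193	0.09	54705	0.16	307863	0.90	8421998	24.63
Q5	T	35779358	8384	0.02	297959	0.83	8508	0.02	30761	0.09	21985915	61.45	2656228	7.42	49736	0.14	116160	0.32	167169	0.47	270220	0.76	1596387	4.46	8590786	24.01
S1	N	32055346	6117	0.02	1845217	5.76	12057	0.04	60258	0.19	17015120	53.08	6283167	19.60	68725	0.21	24960	0.08	104261	0.33	234082	0.73	350428	1.09	6050477	18.88
S1	T	41112010	17603	0.04	3936180	9.57	44451	0.11	251699	0.61	8314806	20.22	20102292	48.90	344943	0.84	69247	0.17	428991	1.04	986772	2.40	672186	1.64	5940943	14.45
S2	N	29397073	3898	0.01	897203	3.05	7963	0.03	46597	0.16	19689931	66.98	3052566	10.38	62226	0.21	16824	0.06	56902	0.19	108604	0.37	186500	0.63	5267657	17.92
S2	T	26137643	13962	0.05	295974	1.13	16398	0.06	95037	0.36	10893729	41.68	7311047	27.97	129995	0.50	61762	0.24	212641	0.81	494207	1.89	912770	3.49	5699007	21.80
S3	N	27264478	4766	0.02	226353	0.83	15660	0.06	39350	0.14	18702182	68.60	2369035	8.69	92587	0.34	30752	0.11	57087	0.21	127926	0.47	230624	0.85	5367833	19.69
S3	T	30690489	9707	0.03	2599251	8.47	17755	0.06	99710	0.32	16952101	55.24	4516427	14.72	116291	0.38	44387	0.14	183781	0.60	415388	1.35	349767	1.14	5385487	17.55
S4	N	42147101	11918	0.03	333573	0.79	7982	0.02	43044	0.10	31240514	74.12	3129257	7.42	52155	0.12	30886	0.07	64665	0.15	129612	0.31	273707	0.65	6829490	16.20
S4	T	34881814	6136	0.02	71254	0.20	11995	0.03	24355	0.07	25685322	73.64	1061270	3.04	61568	0.18	51806	0.15	27056	0.08	59345	0.17	476327	1.37	7345173	21.06
S5	N	47111742	2764	0.01	495709	1.05	11953	0.03	31017	0.07	35338827	75.01	1482687	3.15	61971	0.13	70137	0.15	56524	0.12	127766	0.27	462461	0.98	8969539	19.04
S5	T	35434376	4534	0.01	254597	0.72	10168	0.03	39678	0.11	24840095	70.10	3051937	8.61	65451	0.18	45425	0.13	41078	0.12	107746	0.30	978442	2.76	5994715	16.92
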