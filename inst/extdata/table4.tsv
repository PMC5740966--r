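patient	tissue	edited	wildtype	pct
Q1	N	5321896	21198776	25.10
Q1	T	7787197	19220573	28.83
Q2	N	5823249	15969875	26.72
Q2	T	7467449	18853718	28.37
Q3	N	8579821	23983810	26.35
Q3	T	9210644	19298828	32.30
Q4	N	8076872	34118648	19.14
Q4	T	7532111	24404950	23.58
Q5	N	6186388	22761105	21.37
Q5	T	8750023	22044971	28.41
S1	N	10050073	17020307	37.13
S1	T	4820530	8264552	36.83
S2	N	8645936	19689897	30.51
S2	T	5213543	10899980	32.36
S3	N	6020810	18710729	24.34
S3	T	7471140	16950204	30.59
S4	N	12781917	31251537	29.03
S4	T	6021975	25742476	18.96
S5	N	11084722	35390547	23.85
S5	T	13259479	24854309	34.79
Total	N	82571684	240095231	25.59
Total	T	77534091	190534561	28.92
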