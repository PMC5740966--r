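patient	tissue	edited	wildtype	pct
Q1	N	240370	87935	73.22
Q1	T	557205	44596	92.59
Q2	N	446002	64943	87.29
Q2	T	854634	32478	96.34
Q3	N	212470	9154	95.87
Q3	T	354812	8077	97.77
Q4	N	151335	8809	94.50
Q4	T	92280	3395	96.45
Q5	N	116611	17170	87.17
Q5	T	142264	7492	95.00
S1	N	535538	27674	95.09
S1	T	197120	11975	94.27
S2	N	298654	21904	93.17
S2	T	296729	16490	94.74
S3	N	174168	20140	89.64
S3	T	203879	15356	93.00
S4	N	115859	8238	93.36
S4	T	83231	4713	94.64
S5	N	235026	12658	94.89
S5	T	194898	14228	93.20
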