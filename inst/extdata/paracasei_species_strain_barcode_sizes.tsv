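idx	strain	phylogroup	species_specific_kmers	strain_specific_kmers	retained
1	MGB0747	I	1201260	83	FALSE
2	MGB0761	I	1201306	81	FALSE
3	L9	I	1186502	0	FALSE
4	MGYG-HGUT	I	1186506	0	FALSE
5	NJ	I	1188566	17470	TRUE
6	347-16	I	1207017	130	FALSE
7	CACC 566	I	1207087	216	FALSE
8	Lp02	I	1177634	11840	TRUE
9	IJH-SONE68	I	1183896	26679	TRUE
10	IIA	I	1198699	16607	TRUE
11	subsp 10266	I	1172488	25784	TRUE
12	ZY-1	I	1216121	46665	TRUE
13	LC355	I	1179984	17903	TRUE
14	SRCM 103299	I	1194448	23021	TRUE
15	HD1.7	I	1201260	83	FALSE
16	HDS-01	I	1201306	81	FALSE
17	MGB0734	-	1178026	65524	TRUE
18	Zhang	II	1143566	8885	FALSE
19	LOCK919	II	1230630	28394	TRUE
20	ZFM54	II	1169160	22145	TRUE
21	TK1501	II	1154098	19871	TRUE
22	12A	II	1103714	28753	TRUE
23	subsp. 8700:2	II	1184388	23564	TRUE
24	Lpc10	II	1179984	39486	TRUE
25	MGB0245	III	1184705	50602	TRUE
26	MGB0625	III	1228586	48092	TRUE
27	TK-P4A	III	1212483	86180	TRUE
28	TMW 1.1434	III	1199252	25090	TRUE
29	IBB3423	III	1250212	38367	TRUE
30	CBA3611	III	1188329	89	FALSE
31	LC2W	III	1188152	38	FALSE
32	subsp. 7112-2	III	1182816	121	FALSE
33	BL23	III	1199366	427	FALSE
34	W56	III	1199237	571	FALSE
35	BD-II	III	1199063	144	FALSE
36	TCS	III	1199506	244	FALSE
37	NFFJ04	-	1155507	71319	TRUE
38	NSMJ15	-	1060651	77519	TRUE
39	VKM B-1144	-	1100024	73388	TRUE
40	TD 062	IV	1000877	22825	TRUE
41	FAM18149	IV	1028072	28405	TRUE
42	CAUH35	IV	1052575	38375	TRUE
43	ATCC 334	IV	1143681	38932	TRUE
44	EG9	IV	1093799	37831	TRUE
45	N1115	IV	1105817	25748	TRUE
46	KL1	IV	1165966	20265	TRUE
47	JCM 8130	IV	1134441	43983	TRUE
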