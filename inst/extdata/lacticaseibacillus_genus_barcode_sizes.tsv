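idx	strain	species	phylogroup	genus_specific_kmers
1	MGB0747	L. paracasei	I	1342841
2	MGB0761	L. paracasei	I	1342893
3	L9	L. paracasei	I	1326474
4	MGYG-HGUT-02388	L. paracasei	I	1326474
5	NJ	L. paracasei	I	1335035
6	347-16	L. paracasei	I	1354652
7	CACC 566	L. paracasei	I	1354718
8	Lp02	L. paracasei	I	1307893
9	IJH-SONE68	L. paracasei	I	1316002
10	IIA	L. paracasei	I	1334702
11	10266	L. paracasei	I	1306215
12	ZY-1	L. paracasei	I	1354745
13	LC355	L. paracasei	I	1311398
14	SRCM103299	L. paracasei	I	1333804
15	HDS-01	L. paracasei	I	1310186
16	HD1-7	L. paracasei	I	1310389
17	Zhang	L. paracasei	II	1267650
18	LOCK919	L. paracasei	II	1373093
19	ZFM54	L. paracasei	II	1310426
20	TK1501	L. paracasei	II	1289097
21	12A	L. paracasei	II	1301297
22	8700:2	L. paracasei	II	1319012
23	Lpc10	L. paracasei	II	1345201
24	MGB0245	L. paracasei	III	1331017
25	MGB0625	L. paracasei	III	1391072
26	TK-P4A	L. paracasei	III	1352170
27	TMW 1-1434	L. paracasei	III	1323010
28	IBB3423	L. paracasei	III	1400224
29	CBA3611	L. paracasei	III	1316237
30	LC2W	L. paracasei	III	1316047
31	AO356 (7112-2)	L. paracasei	III	1310307
32	BL23	L. paracasei	III	1337551
33	W56	L. paracasei	III	1337353
34	BD-II	L. paracasei	III	1337137
35	TCS	L. paracasei	III	1337717
36	TD 062	L. paracasei	IV	1129425
37	FAM18149	L. paracasei	IV	1162779
38	CAUH35	L. paracasei	IV	1187210
39	ATCC 334	L. paracasei	IV	1229640
40	EG9	L. paracasei	IV	1243018
41	N1115	L. paracasei	IV	1235840
42	KL1	L. paracasei	IV	1234653
43	JCM 8130	L. paracasei	IV	1286351
44	MGB0734	L. paracasei	-	1327753
45	NFFJ04	L. paracasei	-	1287217
46	VKM B-1144	L. paracasei	-	1274372
47	NSMJ15	L. paracasei	-	1208720
48	ATCC 393	L. casei	-	1216652
49	LC5	L. casei	-	1398284
50	CECT 9104	L. zeae	-	1326946
51	LM010	L. manihotivorans	-	1381360
52	4B15	L. rhamnosus	-	1357067
53	GG	L. rhamnosus	-	1357107
54	BIO6870	L. rhamnosus	-	1356905
55	LR-B1	L. rhamnosus	-	1357098
56	WQ2	L. rhamnosus	-	1351500
57	LRB	L. rhamnosus	-	1333164
58	hsryfm 1301	L. rhamnosus	-	1352189
59	DSM 14870	L. rhamnosus	-	1346181
60	IDCC 3201	L. rhamnosus	-	1323375
61	BFE5264	L. rhamnosus	-	1338512
62	1-0320	L. rhamnosus	-	1350218
63	LR5	L. rhamnosus	-	1370793
64	LOCK900	L. rhamnosus	-	1332726
65	Pen	L. rhamnosus	-	1329920
66	BPL5	L. rhamnosus	-	1392367
67	ATCC 8530	L. rhamnosus	-	1362386
68	Lc 705	L. rhamnosus	-	1377678
69	ASCC 290	L. rhamnosus	-	1357004
70	SCT-10-10-60	L. rhamnosus	-	1377318
71	ATCC 11443	L. rhamnosus	-	1377473
72	LOCK908	L. rhamnosus	-	1377399
73	NCTC13764	L. rhamnosus	-	1377359
74	BIO5326	L. rhamnosus	-	1377176
75	NCTC13710	L. rhamnosus	-	1377380
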