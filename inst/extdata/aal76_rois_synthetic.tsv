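index	abbreviation	name	hemisphere	network
0	PRE.L	Precentral gyrus	L	SMN
1	PRE.R	Precentral gyrus	R	SMN
2	F1.L	Superior frontal gyrus, dorsolateral	L	OTHER
3	F1.R	Superior frontal gyrus, dorsolateral	R	OTHER
4	F1O.L	Superior frontal gyrus, orbital part	L	OTHER
5	F1O.R	Superior frontal gyrus, orbital part	R	OTHER
6	F2.L	Middle frontal gyrus	L	DAN
7	F2.R	Middle frontal gyrus	R	DAN
8	F2O.L	Middle frontal gyrus, orbital part	L	OTHER
9	F2O.R	Middle frontal gyrus, orbital part	R	OTHER
10	F3OP.L	Inferior frontal gyrus, opercular part	L	OTHER
11	F3OP.R	Inferior frontal gyrus, opercular part	R	OTHER
12	F3T.L	Inferior frontal gyrus, triangular part	L	OTHER
13	F3T.R	Inferior frontal gyrus, triangular part	R	OTHER
14	F3O.L	Inferior frontal gyrus, orbital part	L	OTHER
15	F3O.R	Inferior frontal gyrus, orbital part	R	OTHER
16	RO.L	Rolandic operculum	L	OTHER
17	RO.R	Rolandic operculum	R	OTHER
18	SMA.L	Supplementary motor area	L	SMN
19	SMA.R	Supplementary motor area	R	SMN
20	OC.L	Olfactory cortex	L	OTHER
21	OC.R	Olfactory cortex	R	OTHER
22	F1M.L	Superior frontal gyrus, medial	L	DMN
23	F1M.R	Superior frontal gyrus, medial	R	DMN
24	F1MO.L	Superior frontal gyrus, medial orbital	L	DMN
25	F1MO.R	Superior frontal gyrus, medial orbital	R	DMN
26	GR.L	Gyrus rectus	L	OTHER
27	GR.R	Gyrus rectus	R	OTHER
28	IN.L	Insula	L	OTHER
29	IN.R	Insula	R	OTHER
30	ACIN.L	Anterior cingulate and paracingulate gyri	L	DMN
31	ACIN.R	Anterior cingulate and paracingulate gyri	R	DMN
32	MCIN.L	Median cingulate and paracingulate gyri	L	OTHER
33	MCIN.R	Median cingulate and paracingulate gyri	R	OTHER
34	PCIN.L	Posterior cingulate gyrus	L	DMN
35	PCIN.R	Posterior cingulate gyrus	R	DMN
36	V1.L	Calcarine fissure and surrounding cortex	L	VN
37	V1.R	Calcarine fissure and surrounding cortex	R	VN
38	Q.L	Cuneus	L	VN
39	Q.R	Cuneus	R	VN
40	LING.L	Lingual gyrus	L	VN
41	LING.R	Lingual gyrus	R	VN
42	O1.L	Superior occipital gyrus	L	VN
43	O1.R	Superior occipital gyrus	R	VN
44	O2.L	Middle occipital gyrus	L	VN
45	O2.R	Middle occipital gyrus	R	VN
46	O3.L	Inferior occipital gyrus	L	VN
47	O3.R	Inferior occipital gyrus	R	VN
48	FUSI.L	Fusiform gyrus	L	VN
49	FUSI.R	Fusiform gyrus	R	VN
50	POST.L	Postcentral gyrus	L	SMN
51	POST.R	Postcentral gyrus	R	SMN
52	P1.L	Superior parietal gyrus	L	DAN
53	P1.R	Superior parietal gyrus	R	DAN
54	P2.L	Inferior parietal gyrus	L	OTHER
55	P2.R	Inferior parietal gyrus	R	OTHER
56	SMG.L	Supramarginal gyrus	L	OTHER
57	SMG.R	Supramarginal gyrus	R	OTHER
58	AG.L	Angular gyrus	L	DMN
59	AG.R	Angular gyrus	R	DMN
60	PQ.L	Precuneus	L	DMN
61	PQ.R	Precuneus	R	DMN
62	PCL.L	Paracentral lobule	L	SMN
63	PCL.R	Paracentral lobule	R	SMN
64	HES.L	Heschl gyrus	L	AN
65	HES.R	Heschl gyrus	R	AN
66	T1.L	Superior temporal gyrus	L	AN
67	T1.R	Superior temporal gyrus	R	AN
68	T1P.L	Temporal pole: superior temporal gyrus	L	OTHER
69	T1P.R	Temporal pole: superior temporal gyrus	R	OTHER
70	T2.L	Middle temporal gyrus	L	DMN
71	T2.R	Middle temporal gyrus	R	DMN
72	T2P.L	Temporal pole: middle temporal gyrus	L	OTHER
73	T2P.R	Temporal pole: middle temporal gyrus	R	OTHER
74	T3.L	Inferior temporal gyrus	L	OTHER
75	T3.R	Inferior temporal gyrus	R	OTHER
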