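index	name	hemisphere
1	Precentral L	left
2	Precentral R	right
3	Frontal Sup L	left
4	Frontal Sup R	right
5	Frontal Sup Orb L	left
6	Frontal Sup Orb R	right
7	Frontal Mid L	left
8	Frontal Mid R	right
9	Frontal Mid Orb L	left
10	Frontal Mid Orb R	right
11	Frontal Inf Oper L	left
12	Frontal Inf Oper R	right
13	Frontal Inf Tri L	left
14	Frontal Inf Tri R	right
15	Frontal Inf Orb L	left
16	Frontal Inf Orb R	right
17	Rolandic Oper L	left
18	Rolandic Oper R	right
19	Supp Motor Area L	left
20	Supp Motor Area R	right
21	Olfactory L	left
22	Olfactory R	right
23	Frontal Sup Medial L	left
24	Frontal Sup Medial R	right
25	Frontal Med Orb L	left
26	Frontal Med Orb R	right
27	Rectus L	left
28	Rectus R	right
29	Insula L	left
30	Insula R	right
31	Cingulum Ant L	left
32	Cingulum Ant R	right
33	Cingulum Mid L	left
34	Cingulum Mid R	right
35	Cingulum Post L	left
36	Cingulum Post R	right
37	Hippocampus L	left
38	Hippocampus R	right
39	ParaHippocampal L	left
40	ParaHippocampal R	right
41	Amygdala L	left
42	Amygdala R	right
43	Calcarine L	left
44	Calcarine R	right
45	Cuneus L	left
46	Cuneus R	right
47	Lingual L	left
48	Lingual R	right
49	Occipital Sup L	left
50	Occipital Sup R	right
51	Occipital Mid L	left
52	Occipital Mid R	right
53	Occipital Inf L	left
54	Occipital Inf R	right
55	Fusiform L	left
56	Fusiform R	right
57	Postcentral L	left
58	Postcentral R	right
59	Parietal Sup L	left
60	Parietal Sup R	right
61	Parietal Inf L	left
62	Parietal Inf R	right
63	SupraMarginal L	left
64	SupraMarginal R	right
65	Angular L	left
66	Angular R	right
67	Precuneus L	left
68	Precuneus R	right
69	Paracentral Lobule L	left
70	Paracentral Lobule R	right
71	Caudate L	left
72	Caudate R	right
73	Putamen L	left
74	Putamen R	right
75	Pallidum L	left
76	Pallidum R	right
77	Thalamus L	left
78	Thalamus R	right
79	Heschl L	left
80	Heschl R	right
81	Temporal Sup L	left
82	Temporal Sup R	right
83	Temporal Pole Sup L	left
84	Temporal Pole Sup R	right
85	Temporal Mid L	left
86	Temporal Mid R	right
87	Temporal Pole Mid L	left
88	Temporal Pole Mid R	right
89	Temporal Inf L	left
90	Temporal Inf R	right
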