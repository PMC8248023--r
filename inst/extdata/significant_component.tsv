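index1	name1	index2	name2	difference
77	Thalamus L	74	Putamen R	0.008
78	Thalamus R	73	Putamen L	0.009
76	Pallidum R	73	Putamen L	0.009
77	Thalamus L	33	Cingulum Mid L	0.013
73	Putamen L	31	Cingulum Ant L	0.013
78	Thalamus R	77	Thalamus L	0.019
34	Cingulum Mid R	33	Cingulum Mid L	0.044
78	Thalamus R	72	Caudate R	-0.088
34	Cingulum Mid R	20	Supp Motor Area R	-0.040
72	Caudate R	4	Frontal Sup R	-0.028
34	Cingulum Mid R	32	Cingulum Ant R	-0.026
72	Caudate R	24	Frontal Sup Medial R	-0.022
71	Caudate L	3	Frontal Sup L	-0.016
73	Putamen L	7	Frontal Mid L	-0.014
24	Frontal Sup Medial R	3	Frontal Sup L	-0.011
77	Thalamus L	7	Frontal Mid L	-0.010
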