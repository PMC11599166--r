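index	abbreviation	name
1	PreCG.L	Precentral_L
2	PreCG.R	Precentral_R
3	SFGdor.L	Frontal_Sup_L
4	SFGdor.R	Frontal_Sup_R
5	ORBsup.L	Frontal_Sup_Orb_L
6	ORBsup.R	Frontal_Sup_Orb_R
7	MFG.L	Frontal_Mid_L
8	MFG.R	Frontal_Mid_R
9	ORBmid.L	Frontal_Mid_Orb_L
10	ORBmid.R	Frontal_Mid_Orb_R
11	IFGoperc.L	Frontal_Inf_Oper_L
12	IFGoperc.R	Frontal_Inf_Oper_R
13	IFGtriang.L	Frontal_Inf_Tri_L
14	IFGtriang.R	Frontal_Inf_Tri_R
15	ORBinf.L	Frontal_Inf_Orb_L
16	ORBinf.R	Frontal_Inf_Orb_R
17	ROL.L	Rolandic_Oper_L
18	ROL.R	Rolandic_Oper_R
19	SMA.L	Supp_Motor_Area_L
20	SMA.R	Supp_Motor_Area_R
21	OLF.L	Olfactory_L
22	OLF.R	Olfactory_R
23	SFGmed.L	Frontal_Sup_Medial_L
24	SFGmed.R	Frontal_Sup_Medial_R
25	ORBsupmed.L	Frontal_Med_Orb_L
26	ORBsupmed.R	Frontal_Med_Orb_R
27	REC.L	Rectus_L
28	REC.R	Rectus_R
29	INS.L	Insula_L
30	INS.R	Insula_R
31	ACG.L	Cingulum_Ant_L
32	ACG.R	Cingulum_Ant_R
33	DCG.L	Cingulum_Mid_L
34	DCG.R	Cingulum_Mid_R
35	PCG.L	Cingulum_Post_L
36	PCG.R	Cingulum_Post_R
37	HIP.L	Hippocampus_L
38	HIP.R	Hippocampus_R
39	PHG.L	ParaHippocampal_L
40	PHG.R	ParaHippocampal_R
41	AMYG.L	Amygdala_L
42	AMYG.R	Amygdala_R
43	CAL.L	Calcarine_L
44	CAL.R	Calcarine_R
45	CUN.L	Cuneus_L
46	CUN.R	Cuneus_R
47	LING.L	Lingual_L
48	LING.R	Lingual_R
49	SOG.L	Occipital_Sup_L
50	SOG.R	Occipital_Sup_R
51	MOG.L	Occipital_Mid_L
52	MOG.R	Occipital_Mid_R
53	IOG.L	Occipital_Inf_L
54	IOG.R	Occipital_Inf_R
55	FFG.L	Fusiform_L
56	FFG.R	Fusiform_R
57	PoCG.L	Postcentral_L
58	PoCG.R	Postcentral_R
59	SPG.L	Parietal_Sup_L
60	SPG.R	Parietal_Sup_R
61	IPL.L	Parietal_Inf_L
62	IPL.R	Parietal_Inf_R
63	SMG.L	SupraMarginal_L
64	SMG.R	SupraMarginal_R
65	ANG.L	Angular_L
66	ANG.R	Angular_R
67	PCUN.L	Precuneus_L
68	PCUN.R	Precuneus_R
69	PCL.L	Paracentral_Lobule_L
70	PCL.R	Paracentral_Lobule_R
71	CAU.L	Caudate_L
72	CAU.R	Caudate_R
73	PUT.L	Putamen_L
74	PUT.R	Putamen_R
75	PAL.L	Pallidum_L
76	PAL.R	Pallidum_R
77	THA.L	Thalamus_L
78	THA.R	Thalamus_R
79	HES.L	Heschl_L
80	HES.R	Heschl_R
81	STG.L	Temporal_Sup_L
82	STG.R	Temporal_Sup_R
83	TPOsup.L	Temporal_Pole_Sup_L
84	TPOsup.R	Temporal_Pole_Sup_R
85	MTG.L	Temporal_Mid_L
86	MTG.R	Temporal_Mid_R
87	TPOmid.L	Temporal_Pole_Mid_L
88	TPOmid.R	Temporal_Pole_Mid_R
89	ITG.L	Temporal_Inf_L
90	ITG.R	Temporal_Inf_R
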