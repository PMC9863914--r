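smq_name	smq_code	n	ic	ic025	ic975	ror	ror025	ror975
Supraventricular tachyarrhythmias	20000057	2557	3.09	3.02	3.13	8.49	8.16	8.83
Haemorrhagic central nervous system vascular conditions	20000064	1080	2.13	2.03	2.2	4.37	4.11	4.64
Ventricular tachyarrhythmias	20000058	226	1.18	0.96	1.34	2.27	1.99	2.58
Cardiac failure	20000004	1887	0.92	0.84	0.97	1.89	1.8	1.98
Ischaemic central nervous system vascular conditions	20000063	899	0.74	0.63	0.82	1.67	1.57	1.79
Disorders of sinus node function	20000055	51	0.53	0.07	0.87	1.45	1.1	1.91
Cardiomyopathy	20000150	2641	0.49	0.43	0.54	1.41	1.35	1.46
Conduction defects	20000056	130	0.49	0.2	0.7	1.4	1.18	1.66
Myocardial infarction	20000047	629	0.26	0.12	0.35	1.19	1.1	1.29
Torsade de pointes/QT prolongation	20000001	1104	0.17	0.07	0.24	1.12	1.06	1.19
Embolic and thrombotic events, arterial	20000082	136	0	-0.28	0.21	1	0.85	1.19
Embolic and thrombotic events, venous	20000083	433	0	-0.16	0.12	1	0.91	1.1
Hypertension	20000147	1299	-0.05	-0.14	0.02	0.97	0.92	1.02
Conditions associated with central nervous system haemorrhages and cerebrovascular accidents	20000166	200	-0.17	-0.41	0	0.89	0.77	1.02
Pulmonary hypertension	20000130	1436	-0.38	-0.47	-0.32	0.77	0.73	0.81
Embolic and thrombotic events, vessel type unspecified and mixed arterial and venous	20000168	344	-0.67	-0.85	-0.54	0.63	0.56	0.7
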