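locus	na	ne	i	ho	he	f	pic
234	8	3.76	1.58	0.70	0.73	0.05	0.69
478	5	3.75	1.39	0.40	0.73	0.46	0.69
A5	4	1.58	0.72	0.44	0.37	-0.20	0.34
CsFM1051	9	5.45	1.89	0.76	0.82	0.07	0.79
CsFM1058	8	4.74	1.71	0.69	0.79	0.12	0.76
CsFM1068	14	8.41	2.31	0.74	0.88	0.16	0.87
CsFM1158	6	3.19	1.32	0.45	0.69	0.35	0.64
CsFM1599	5	3.78	1.42	0.64	0.74	0.13	0.69
CsFM1696	10	4.34	1.83	0.65	0.77	0.16	0.75
CsFM1715	15	8.28	2.36	0.88	0.88	0.01	0.87
CsFM1828	13	5.00	2.05	0.74	0.80	0.07	0.79
CSK014	9	2.62	1.33	0.44	0.62	0.30	0.58
CSK065	4	1.36	0.54	0.08	0.26	0.69	0.25
SSR1	7	2.61	1.36	0.44	0.62	0.29	0.59
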