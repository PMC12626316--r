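accession	leaf_length_cm	leaf_width_cm	length_width_ratio	leaf_area_cm2	note
S1	15.81	5.49	2.91	60.74	
S2	16.99	5.31	3.23	63.00	
S3	16.16	5.56	2.93	62.79	
S4	16.82	5.25	3.29	61.46	
S5	16.72	5.49	3.14	63.49	
S6	7.87	3.82	2.13	21.29	
S7	7.67	3.86	2.08	20.63	
S8	7.68	2.26	1.84	22.71	
S9	7.47	4.25	1.89	21.86	
S10	7.89	4.07	1.99	22.62	
S11	12.57	2.82	5.00	24.26	
S12	13.13	2.51	5.53	22.97	
S13	13.20	3.03	4.57	27.68	
S14	12.06	3.04	4.26	25.47	
S15	12.35	3.26	3.87	28.30	
S16	12.64	3.05	4.29	27.27	
S17	12.38	3.00	4.44	25.70	area repaired from a doubled decimal point
S18	12.88	3.62	3.59	32.94	
S19	11.41	3.83	3.13	30.77	
S20	14.28	3.07	4.90	30.59	
S21	6.60	2.77	2.57	12.75	
S22	6.96	3.34	2.11	16.30	
S23	7.59	2.91	2.95	15.14	
S24	6.94	2.80	2.82	13.22	
S25	7.64	2.77	2.90	15.02	
S26	12.38	3.15	4.16	27.35	
S27	11.89	3.40	3.78	27.96	
S28	12.58	3.39	3.78	29.93	
S29	11.88	3.09	4.02	25.60	
S30	13.35	2.69	5.11	24.97	
S31	5.97	2.89	2.16	12.39	width repaired from run-together digits
S32	6.47	2.65	2.53	12.08	
S33	5.65	2.75	2.10	11.06	
S34	5.96	0.94	2.32	12.08	width retained as printed but suspect
S35	6.84	2.61	2.82	12.20	
S36	7.91	4.50	1.87	24.42	
S37	7.61	4.38	1.77	23.15	
S38	8.09	4.52	1.89	25.13	
S39	8.36	4.43	2.00	25.70	
S40	8.20	3.75	2.26	21.19	
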