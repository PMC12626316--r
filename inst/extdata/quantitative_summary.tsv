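trait	min	max	mean	sd	cv_pct	shannon
leaf_length_cm	4.66	18.25	10.42	3.56	34.14	1.91
leaf_width_cm	1.78	6.57	3.61	1.15	31.91	1.90
length_width_ratio	1.17	7.60	3.12	1.34	42.81	1.93
leaf_area_cm2	7.93	69.68	27.10	15.41	56.86	1.70
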