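trait	f1	f2	f3	f4	f5	cv_pct	shannon	h_consistent	cv_consistent
Tree type	0.00	87.50	12.50	NA	NA	15.76	0.38	TRUE	TRUE
Tree posture	50.00	40.00	10.00	NA	NA	41.99	0.71	FALSE	TRUE
Branch density	62.50	25.00	12.50	NA	NA	47.74	0.90	TRUE	TRUE
Bud and leaf color	0.00	37.50	50.00	12.50	0.00	24.36	0.97	TRUE	TRUE
Bud and leaf pubescence	12.50	50.00	27.50	10.00	0.00	35.47	0.70	FALSE	TRUE
Leaf blade shape	0.00	5.00	7.50	62.50	25.00	17.91	0.83	FALSE	TRUE
Leaf blade color	37.50	37.50	12.50	12.50	NA	50.64	1.00	FALSE	TRUE
Leaf surface relief	25.00	60.00	15.00	NA	NA	32.38	0.94	TRUE	FALSE
Leaf blade curvature	12.50	42.50	45.00	NA	NA	29.68	0.98	TRUE	FALSE
Leaf blade texture	12.50	62.50	25.00	NA	NA	28.57	0.90	TRUE	TRUE
Serration sharpness	25.00	50.00	25.00	NA	NA	35.81	1.04	TRUE	TRUE
Serration density	15.00	47.50	37.50	NA	NA	29.77	1.01	TRUE	FALSE
Serration depth	40.00	47.50	12.50	NA	NA	39.36	0.72	FALSE	TRUE
Leaf base shape	87.50	12.50	NA	NA	NA	29.77	0.38	TRUE	TRUE
Leaf apex shape	10.00	40.00	35.00	15.00	NA	34.34	1.02	FALSE	TRUE
Leaf margin undulation	40.00	47.50	12.50	NA	NA	38.28	0.98	TRUE	FALSE
Leaf attitude	12.50	75.00	12.50	0.00	NA	25.32	0.74	TRUE	TRUE
Leaf size	25.00	62.50	12.50	0.00	NA	32.38	1.00	FALSE	TRUE
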