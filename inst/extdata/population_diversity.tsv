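population	mean_na	mean_ne	pct_effective	mean_i	mean_ho	mean_he
CQ	5.50	3.71	67.36	1.34	0.64	0.65
LT	2.43	2.15	88.35	0.74	0.53	0.46
JB	3.57	2.94	82.33	1.07	0.70	0.60
NN	2.64	2.04	77.26	0.70	0.51	0.40
RX	3.50	2.79	79.60	1.00	0.59	0.54
QS	2.29	1.81	79.05	0.60	0.45	0.36
XL	2.57	2.13	82.69	0.76	0.53	0.46
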