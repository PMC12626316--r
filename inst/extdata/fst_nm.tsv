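population	CQ	LT	JB	NN	RX	QS	XL
CQ	NA	1.98	4.06	1.69	2.69	0.71	2.53
LT	0.11	NA	2.30	0.86	1.34	0.42	1.17
JB	0.06	0.10	NA	1.35	2.69	0.57	1.83
NN	0.13	0.23	0.16	NA	1.09	0.41	1.41
RX	0.09	0.16	0.09	0.19	NA	0.68	1.18
QS	0.26	0.37	0.31	0.38	0.27	NA	0.52
XL	0.09	0.18	0.12	0.15	0.18	0.32	NA
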