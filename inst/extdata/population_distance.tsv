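population	CQ	LT	JB	NN	RX	QS	XL
CQ	0	0.32	0.25	0.35	0.30	0.68	0.30
LT	0.32	0	0.25	0.41	0.33	0.74	0.41
JB	0.25	0.25	0	0.34	0.24	0.70	0.34
NN	0.35	0.41	0.34	0	0.45	0.69	0.30
RX	0.30	0.33	0.24	0.45	0	0.65	0.45
QS	0.68	0.74	0.70	0.69	0.65	0	0.66
XL	0.30	0.41	0.34	0.30	0.45	0.66	0
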