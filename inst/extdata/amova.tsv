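stratum	df	ss	ms	sigma2	pct
Among populations	6	99.29	16.55	1.08	20.46
Among individuals within populations	33	147.15	4.46	0.28	5.32
Within individuals	40	156.00	3.90	3.90	74.22
Total	79	402.44	NA	5.26	100.00
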