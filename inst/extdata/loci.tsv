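name	repeat_motif	repeat_count	anneal_temp_c	expected_size_bp
CSK014	TATC	8	58	128
CSK065	ATT	20	59	274
CsFM1715	TG	14	56	165
CsFM1051	TTG	8	57	124
CsFM1068	TTC	11	56	212
CsFM1058	TTC	9	57	162
CsFM1599	CCTTC	5	56	167
CsFM1828	CAT	7	57	116
CsFM1696	ACC	8	55	249
478	AAAGG	4	51	110
CsFM1158	CACACC	6	56	220
SSR1	CA	8	52	153
A5	AG	12	54	119
234	AAAAAG	3	53	151
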