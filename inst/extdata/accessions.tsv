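accession	population	population_name	location	elevation_m
S1	QS	Qingshan	Qingshan Village	716.53
S2	QS	Qingshan	Qingshan Village	716.53
S3	QS	Qingshan	Qingshan Village	716.53
S4	QS	Qingshan	Qingshan Village	716.53
S5	QS	Qingshan	Qingshan Village	716.53
S6	RX	Raoxiu	Raoxiu Village	702.24
S7	RX	Raoxiu	Raoxiu Village	702.24
S8	RX	Raoxiu	Raoxiu Village	702.24
S9	RX	Raoxiu	Raoxiu Village	702.24
S10	RX	Raoxiu	Raoxiu Village	702.24
S11	CQ	Changqiao	Changqiao Village	650.61
S12	CQ	Changqiao	Changqiao Village	650.61
S13	CQ	Changqiao	Changqiao Village	650.61
S14	CQ	Changqiao	Changqiao Village	650.61
S15	CQ	Changqiao	Changqiao Village	650.61
S16	CQ	Changqiao	Changqiao Village	650.61
S17	CQ	Changqiao	Changqiao Village	650.61
S18	CQ	Changqiao	Changqiao Village	650.61
S19	CQ	Changqiao	Changqiao Village	650.61
S20	CQ	Changqiao	Changqiao Village	650.61
S21	XL	Xinlin	Xinlin Village	308.23
S22	XL	Xinlin	Xinlin Village	308.23
S23	XL	Xinlin	Xinlin Village	308.23
S24	XL	Xinlin	Xinlin Village	308.23
S25	XL	Xinlin	Xinlin Village	308.23
S26	LT	Liutou	Liutou Village	540.22
S27	LT	Liutou	Liutou Village	540.22
S28	LT	Liutou	Liutou Village	540.22
S29	LT	Liutou	Liutou Village	540.22
S30	LT	Liutou	Liutou Village	540.22
S31	NN	Nanei	Nanei Village	440.51
S32	NN	Nanei	Nanei Village	440.51
S33	NN	Nanei	Nanei Village	440.51
S34	NN	Nanei	Nanei Village	440.51
S35	NN	Nanei	Nanei Village	440.51
S36	JB	Jiangbian	Jiangbian Village	340.50
S37	JB	Jiangbian	Jiangbian Village	340.50
S38	JB	Jiangbian	Jiangbian Village	340.50
S39	JB	Jiangbian	Jiangbian Village	340.50
S40	JB	Jiangbian	Jiangbian Village	340.50
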