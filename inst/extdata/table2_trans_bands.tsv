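band	sdp	chromosome	peak_mbp	left_mbp	right_mbp	n_eqtls
TB1	14	I	1.03	0.03	2.03	1339
TB2	JU1511	I	0.83	0	1.83	443
TB3	JU1931	V	10.74	9.74	11.74	607
TB4	JU1511	X	3.40	2.40	4.40	133
TB5	JU1941	X	14.69	13.69	15.64	225
TB6	JU1941	X	16.60	15.65	17.6	957
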