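sdp	type	chromosome	n
12	cis	I	14
12	cis	II	2
12	cis	III	17
12	cis	IV	2
12	cis	V	23
12	cis	X	13
12	trans	I	35
12	trans	II	0
12	trans	III	1
12	trans	IV	1
12	trans	V	3
12	trans	X	67
13	cis	I	6
13	cis	II	1
13	cis	III	14
13	cis	IV	39
13	cis	V	41
13	cis	X	3
13	trans	I	0
13	trans	II	2
13	trans	III	106
13	trans	IV	13
13	trans	V	15
13	trans	X	27
14	cis	I	12
14	cis	II	0
14	cis	III	19
14	cis	IV	0
14	cis	V	53
14	cis	X	11
14	trans	I	1373
14	trans	II	0
14	trans	III	119
14	trans	IV	5
14	trans	V	103
14	trans	X	44
JU1511	cis	I	37
JU1511	cis	II	32
JU1511	cis	III	61
JU1511	cis	IV	14
JU1511	cis	V	18
JU1511	cis	X	81
JU1511	trans	I	457
JU1511	trans	II	28
JU1511	trans	III	211
JU1511	trans	IV	20
JU1511	trans	V	9
JU1511	trans	X	430
JU1926	cis	I	0
JU1926	cis	II	32
JU1926	cis	III	4
JU1926	cis	IV	59
JU1926	cis	V	5
JU1926	cis	X	1
JU1926	trans	I	5
JU1926	trans	II	44
JU1926	trans	III	5
JU1926	trans	IV	26
JU1926	trans	V	10
JU1926	trans	X	5
JU1931	cis	I	8
JU1931	cis	II	0
JU1931	cis	III	15
JU1931	cis	IV	3
JU1931	cis	V	81
JU1931	cis	X	1
JU1931	trans	I	31
JU1931	trans	II	0
JU1931	trans	III	12
JU1931	trans	IV	21
JU1931	trans	V	919
JU1931	trans	X	2
JU1941	cis	I	76
JU1941	cis	II	0
JU1941	cis	III	66
JU1941	cis	IV	5
JU1941	cis	V	38
JU1941	cis	X	22
JU1941	trans	I	150
JU1941	trans	II	1
JU1941	trans	III	155
JU1941	trans	IV	35
JU1941	trans	V	94
JU1941	trans	X	1271
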