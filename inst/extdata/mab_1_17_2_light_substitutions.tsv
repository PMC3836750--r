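position	rat_aa	human_aa
9	A	S
15	L	V
16	E	G
17	E	D
18	I	R
38	L	Q
43	S	A
45	Q	K
59	S	P
66	R	G
70	Q	D
71	Y	F
72	S	T
74	K	T
77	R	S
80	V	P
83	I	F
84	G	A
85	I	T
106	L	I
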