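position	rat_aa	human_aa
19	K	R
42	T	G
75	A	S
76	R	K
77	S	N
83	V	M
84	D	N
93	T	V
115	V	T
116	M	L
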