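chain	position
L	38
L	43
L	45
L	71
H	77
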