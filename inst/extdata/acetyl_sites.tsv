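histone	position
H3	4
H3	9
H3	14
H3	18
H3	23
H3	27
H3	36
H3	56
H3	115
H3	122
H4	5
H4	8
H4	12
H4	16
H4	20
H4	77
H4	79
H2A	5
H2A	9
H2A	13
H2A	21
H2A	36
H2A	119
H2B	5
H2B	12
H2B	15
H2B	20
H2B	24
H2B	85
H2B	108
H2B	118
H2B	120
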