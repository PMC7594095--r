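residue_id	S2
1	0.85
2	0.88
3	0.90
4	0.82
5	0.65
6	0.87
7	0.89
8	0.91
9	0.86
10	0.84
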