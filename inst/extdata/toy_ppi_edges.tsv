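# protein_a	protein_b
UB	UBP1
UB	UBP2
UBP1	S1
UBP1	S2
UBP1	C1
UBP2	S2
UBP2	C1
UBP2	C3
C3	T1
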