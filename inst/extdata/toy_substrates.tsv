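e3_id	substrate_id
E3A	S1
E3A	S2
E3A	S3
E3B	T1
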