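id	compartment
E3A	nucleus
C1	nucleus
C3	membrane
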