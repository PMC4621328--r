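a0	b0	1
a1	b1	2
a2	b2	3
a1	b2	4
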