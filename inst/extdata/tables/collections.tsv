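collection	n_groups	chromosome
A	32	III
B	25	IV
B	18	V
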