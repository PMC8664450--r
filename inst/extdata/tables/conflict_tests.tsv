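strain_a	strain_b	outcome
GE1742	GE2206	fails_to_complement
GE1742	GE2627	fails_to_complement
GE2206	GE2627	fails_to_complement
GE2220	GE2399	fails_to_complement
GE2220	GE1735	fails_to_complement
GE2220	GE2278	complements
GE2278	GE1735	fails_to_complement
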