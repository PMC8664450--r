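group_id	strain_id	allele	preliminary_candidate	mapped_under
gene-28	GE1742	t1461	bckd-1A	none
gene-17	GE2627	t1603	bckd-1A	tDf5
gene-17	GE2206	t1514	bckd-1A	tDf5
gene-15	GE2220	t1516	top-3	tDf5
gene-15	GE2399	t1559	top-3	tDf5
gene-34	GE2278	t1502	top-3	none
gene-35	GE1735	t1470	top-3	none
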