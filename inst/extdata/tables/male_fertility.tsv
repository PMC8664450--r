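strain	allele	gene	phenotype	rescue
GE2627	t1603	bckd-1A	Dead embryos	Yes
GE2206	t1514	bckd-1A	Dead embryos	Yes
GE2840	t1860	C34D4.4	Unfertilized oocytes	Yes
GE2890	t1821	C34D4.4	Unfertilized oocytes	Yes
GE2734	t2029	C56A3.8	Unfertilized oocytes	Yes
GE2487	t2149	C56A3.8	Unfertilized oocytes	Yes
GE2886	t2055	C56A3.8	Unfertilized oocytes	Yes
GE2881	t1744	F56D5.2	Unfertilized oocytes	No
GE2837	t1791	F56D5.2	Unfertilized oocytes	Yes
GE2091	t1772	nstp-2	Dead embryos	No
GE2288	t1835	nstp-2	Dead embryos	Yes
GE2827	t1786	T22B11.1	Unfertilized oocytes [ts]	Yes
GE2895	t1866	T22B11.1	Unfertilized oocytes [ts]	Yes
GE2884	t1755	Y54G2A.73	Unfertilized oocytes	Yes
GE2387	t1913	Y54G2A.73	Unfertilized oocytes	Yes
GE2738	t1833	Y54G2A.73	Unfertilized oocytes	Yes
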