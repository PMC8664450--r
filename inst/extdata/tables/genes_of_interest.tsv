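strain	allele	gene	aa_change	mutant_phenotype	oid
GE1936	t1738	atg-7	W311*	Dead embryos	No
GE1958	t1726	atg-7	Q367*	Dead embryos	No
GE2627	t1603	bckd-1A	W150*	Dead embryos	Yes
GE2206	t1514	bckd-1A	Q161*	Dead embryos	Yes
GE2840	t1860	C34D4.4	W131*	Unfertilized oocytes	N/A
GE2890	t1821	C34D4.4	W101*	Unfertilized oocytes	N/A
GE2734	t2029	C56A3.8	G62E	Unfertilized oocytes	N/A
GE2487	t2149	C56A3.8	P82L	Unfertilized oocytes	N/A
GE2886	t2055	C56A3.8	E243K	Unfertilized oocytes	N/A
GE2122	t2007	cept-2	Splice site	Dead embryos	No
GE2047	t2021	cept-2	W128*	No eggs laid (dead embryos) [ts]	Some
GE2275	t1517	cls-2	R102Q	Dead embryos	N/T
GE2357	t1527	cls-2	G114R	Dead embryos	No
GE1938	t1742	cpt-2	W194*	Dead embryos	No
GE2447	t1879	cpt-2	Q141*	Dead embryos	No
GE2407	t1906	D2096.12	L638*	Dead embryos	Some
GE2499	t1877	D2096.12	Q126*	Dead embryos	Yes
GE2063	t2042	dgtr-1	G310R	Dead embryos	Some
GE2135	t2043	dgtr-1	Splice site	Dead embryos	Yes
GE2541	t2035	dlat-1	P83L	Dead embryos	No
GE2335	t2056	dlat-1	Q419*	Dead embryos	No
GE2402	t1940	F21D5.1	A436V	Dead embryos	Yes
GE2445	t1935	F21D5.1	L539F	Dead embryos	Yes
GE2881	t1744	F56D5.2	S107F	Unfertilized oocytes	N/A
GE2837	t1791	F56D5.2	Q214*	Unfertilized oocytes	N/A
GE2091	t1772	nstp-2	L277H	Dead embryos	No
GE2288	t1835	nstp-2	G131R	Dead embryos	No
GE2391	t1932	perm-5	C454S	Dead embryos	Yes
GE2453	t1900	perm-5	S323P	Dead embryos	Yes
GE2827	t1786	T22B11.1	W35*	Unfertilized oocytes [ts]	N/A
GE2895	t1866	T22B11.1	W356*	Unfertilized oocytes [ts]	N/A
GE2399	t1559	top-3	G59R	Dead embryos	No
GE2220	t1516	top-3	Q602*	Dead embryos	No
GE2512	t1909	trcs-1	E373K	Dead embryos [leaky ts]	Yes
GE1939	t1745	trcs-1	Q242*	No eggs laid (dead embryos) [ts]	Yes
GE2884	t1755	Y54G2A.73	Splice site	Unfertilized oocytes	N/A
GE2387	t1913	Y54G2A.73	R252*	Unfertilized oocytes	N/A
GE2738	t1833	Y54G2A.73	L341*	Unfertilized oocytes	N/A
GE1713	t1433	ZK688.9	W135*	Dead embryos	No
GE2621	t1587	ZK688.9	Splice site	Dead embryos	No
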