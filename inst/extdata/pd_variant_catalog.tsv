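# Default tiered variant catalog: GRCh38, 1-based, VCF allele convention.
# All GBA1 variants are PD risk variants; LRRK2 risk tier is limited to
# R1628P (rs33949390) and G2385R (rs34778348). Severity classes for GBA1
# follow the severe/mild/risk/unknown convention of the GBA1-PD browser.
gene	chrom	pos	ref	alt	protein_label	rsid	tier	gba1_severity
GBA1	chr1	155235843	T	C	N409S	rs76763715	risk	mild
GBA1	chr1	155236366	C	T	E365K	rs2230288	risk	risk
GBA1	chr1	155235846	G	A	T408M	rs75548401	risk	risk
GBA1	chr1	155235252	A	G	L483P	rs421016	risk	severe
GBA1	chr1	155235252	A	C	L483R	NA	risk	severe
GBA1	chr1	155235358	C	G	D448H	rs1064651	risk	severe
GBA1	chr1	155235312	G	A	R463C	rs80356771	risk	severe
GBA1	chr1	155234452	C	T	R496H	rs121908311	risk	mild
GBA1	chr1	155236376	T	G	c.1225-34C>A	rs3115534	risk	unknown
LRRK2	chr12	40340400	G	A	G2019S	rs34637584	pathogenic	not_applicable
LRRK2	chr12	40310434	C	T	R1441C	rs33939927	pathogenic	not_applicable
LRRK2	chr12	40310434	C	G	R1441G	rs33939927	pathogenic	not_applicable
LRRK2	chr12	40310435	G	A	R1441H	rs33995883	pathogenic	not_applicable
LRRK2	chr12	40275160	G	A	R1067Q	rs111501952	likely_pathogenic	not_applicable
LRRK2	chr12	40303495	G	A	R1325Q	rs200526782	likely_pathogenic	not_applicable
LRRK2	chr12	40351381	C	T	L1795F	NA	likely_pathogenic	not_applicable
LRRK2	chr12	40320043	G	C	R1628P	rs33949390	risk	not_applicable
LRRK2	chr12	40363526	G	A	G2385R	rs34778348	risk	not_applicable
SNCA	chr4	89828149	C	T	A53T	rs104893877	pathogenic	not_applicable
VPS35	chr16	46658109	C	T	D620N	rs188286943	pathogenic	not_applicable
RAB32	chr6	146546473	A	C	S71R	NA	pathogenic	not_applicable
PARK7	chr1	7977997	G	C	E64D	rs74315352	pathogenic	not_applicable
PINK1	chr1	20644549	T	C	L347P	rs28940285	pathogenic	not_applicable
PINK1	chr1	20648535	C	T	Q456X	rs45478900	pathogenic	not_applicable
PRKN	chr6	161807855	G	A	R275W	rs34424986	pathogenic	not_applicable
PRKN	chr6	161970127	G	A	T240M	rs137853054	pathogenic	not_applicable
PRKN	chr6	161506148	G	A	P437L	rs149953814	likely_pathogenic	not_applicable
ATP13A2	chr1	16992306	G	A	R449Q	NA	likely_pathogenic	not_applicable
ATP13A2	chr1	16996382	G	A	F182L	NA	likely_pathogenic	not_applicable
DCTN1	chr2	74367816	C	T	G71R	rs72466496	pathogenic	not_applicable
SLC20A2	chr8	42416475	C	T	S113L	NA	likely_pathogenic	not_applicable
RAB39B	chrX	155259163	G	A	L119P	NA	pathogenic	not_applicable
WDR45	chrX	49074540	C	T	R212X	NA	pathogenic	not_applicable
DNAJC6	chr1	65359582	G	A	Q734X	NA	pathogenic	not_applicable
FBXO7	chr22	32478962	C	T	R498X	rs140594913	pathogenic	not_applicable
SYNJ1	chr21	32708312	C	T	R258Q	rs768035575	pathogenic	not_applicable
VPS13C	chr15	61869378	C	T	R153X	NA	pathogenic	not_applicable
JAM2	chr21	25712547	G	A	W79X	NA	likely_pathogenic	not_applicable
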