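chr1	26696015	26782110	ARID1A
chr2	197388515	197435079	SF3B1
chr3	10141777	10153668	BAP1
chr3	52545352	52685933	PBRM1
chr3	179148114	179240093	PIK3CA
chr5	56815574	56892800	MAP3K1
chr5	68215740	68301821	PIK3R1
chr6	151656691	152129619	ESR1
chr7	140719327	140924929	BRAF
chr10	8045378	8075198	GATA3
chr10	87863113	87971930	PTEN
chr11	532242	537287	HRAS
chr11	64803514	64811294	MEN1
chr11	108222484	108369102	ATM
chr12	12715058	12722371	CDKN1B
chr12	25205246	25250929	KRAS
chr12	114670255	114846247	TBX3
chr13	32315474	32400266	BRCA2
chr13	48303748	48481890	RB1
chr14	104769349	104795751	AKT1
chr16	67029116	67101058	CBFB
chr16	67562407	67640276	CTCF
chr16	68737225	68835548	CDH1
chr17	7571719	7590868	TP53
chr17	11924204	12047147	MAP2K4
chr17	15933408	16118874	NCOR1
chr17	31094927	31377677	NF1
chr17	39688094	39728662	ERBB2
chr17	43044295	43125483	BRCA1
chr18	51028394	51085045	SMAD4
chr21	34787801	35049344	RUNX1
chrX	40944888	41094698	USP9X
chrX	44873182	45112779	KDM6A
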