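chrom	pos	ref	alt	gene	in_cosmic	in_tcga_bc	in_tcga_all	exonic
chr3	179234297	A	G	PIK3CA	1	1	1	1
chr17	7578406	C	T	TP53	1	1	1	1
chr10	8060702	G	A	GATA3	1	1	1	1
chr12	25245350	C	A	KRAS	1	0	1	1
chr17	39723966	G	A	ERBB2	1	0	1	1
chr5	56881911	T	C	MAP3K1	0	1	1	0
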