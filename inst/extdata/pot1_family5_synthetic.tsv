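id	chrom	pos	ref	alt	qual	filter_pass	gene	consequence	maf_1kg	maf_exac_nontcga	cadd_phred	gerp	phastcons	phylop	sift	polyphen2_hdiv	polyphen2_hvar	lrt	mutation_taster	mutation_assessor	fathmm	metasvm	metalr	provean	gt_I-1	gt_II-1	gt_II-2	gt_II-3	gt_II-4	gt_II-5	gt_II-6	gt_II-7	gt_II-8	dp_I-1	dp_II-1	dp_II-2	dp_II-3	dp_II-4	dp_II-5	dp_II-6	dp_II-7	dp_II-8
POT1_c85GtoT	7	124532337	G	T	487.29999999999995	TRUE	POT1	missense	.	.	24.100000000000001	5.0999999999999996	0.97999999999999998	4.7999999999999998	D	D	D	D	D	T	D	.	T	D	0	.	1	1	0	1	1	0	1	31	.	34	29	27	36	30	25	33
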