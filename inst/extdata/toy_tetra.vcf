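##fileformat=VCFv4.3
##source=handmade-toy
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4
1	100	snp_a	A	T	.	PASS	.	GT	0/0/0/0	0/0/0/1	0/1/1/1	1/1/1/1
1	200	multi_b	A	T,C	.	PASS	.	GT	0/0/0/0	0/0/1/2	0/0/0/0	0/0/0/0
1	300	indel_c	A	AT	.	PASS	.	GT	0/0/0/0	0/0/0/1	0/0/0/0	0/0/0/0
1	400	snp_d	G	C	.	PASS	.	GT	0/0/1/1	./././.	0/0/0/1	1/1/1/1
1	500	snp_e	C	G	.	PASS	.	GT	0/0/0/0	0/0/0/0	0/0/0/0	0/0/0/0
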