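##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##contig=<ID=chr1,length=100000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	A1	A2	A3	B1	B2	B3
chr1	1001	.	A	G	.	PASS	.	GT	1/1	1/1	1/1	0/0	0/0	0/0
chr1	2002	.	C	T	.	PASS	.	GT	0/0	0/0	0/0	1/1	1/1	1/1
chr1	3003	.	G	A	.	PASS	.	GT	0/1	0/0	1/1	0/0	0/0	0/0
chr1	4004	.	T	TAG	.	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	1/1
chr1	5005	.	A	C	.	PASS	.	GT	1/1	1/1	./.	1/1	1/1	1/1
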