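##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	GS13_I1	GS13_I2	GS13_II1	GS13_II2	GS13_II3	GS13_II4	GS13_II5	GS13_III1	GS13_III2	GS13_III3	GS13_III4	GS13_III5	GS64_I1	GS64_I2	GS64_II1	GS64_II2	GS64_II5	GS64_II4	GS64_III1	GS64_III2	GS64_III3
19	55441902	rs143169084	C	T	.	.	.	GT	./.	./.	0/1	0/1	0/0	0/0	./.	0/1	0/0	0/1	0/1	0/0	./.	./.	./.	./.	./.	./.	./.	./.	./.
19	55449713	rs140797839	G	A	.	.	.	GT	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	0/1	0/0	0/1	./.	0/1	0/1	0/0
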