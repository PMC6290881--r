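# Reconstructed two-family fixture (GS13-like and GS64-like multiplex IBD
# pedigrees); genotype-by-individual detail is a synthetic reconstruction
# matching the reported carrier/non-carrier tallies. Columns: family,
# individual, father, mother, sex (1=M,2=F), phenotype (2=affected,
# 1=unaffected, 0=unknown), whole-exome-sequenced flag.
GS13	GS13_I1	0	0	1	1	0
GS13	GS13_I2	0	0	2	1	0
GS13	GS13_II1	GS13_I1	GS13_I2	1	2	1
GS13	GS13_II2	GS13_I1	GS13_I2	2	1	0
GS13	GS13_II3	GS13_I1	GS13_I2	1	1	0
GS13	GS13_II4	0	0	2	2	0
GS13	GS13_II5	0	0	1	0	0
GS13	GS13_III1	GS13_II1	GS13_II4	1	2	0
GS13	GS13_III2	GS13_II1	GS13_II4	2	1	0
GS13	GS13_III3	GS13_II5	GS13_II2	1	2	1
GS13	GS13_III4	GS13_II5	GS13_II2	2	1	0
GS13	GS13_III5	GS13_II5	GS13_II2	1	1	0
GS64	GS64_I1	0	0	1	1	0
GS64	GS64_I2	0	0	2	1	0
GS64	GS64_II1	GS64_I1	GS64_I2	1	2	0
GS64	GS64_II2	GS64_I1	GS64_I2	2	2	0
GS64	GS64_II5	GS64_I1	GS64_I2	1	2	1
GS64	GS64_II4	0	0	2	0	0
GS64	GS64_III1	GS64_II1	GS64_II4	1	2	1
GS64	GS64_III2	GS64_II1	GS64_II4	2	1	0
GS64	GS64_III3	GS64_II1	GS64_II4	1	1	0
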