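variant	cohort	maf_pct	freq_pct	p	p_corrected	or	ci_low	ci_high
p.S361L	CD	0.100		0.8700	n.s.	1.49	0.35	6.20
p.S361L	UC	0.200		0.0039	0.0234	4.79	1.60	14.00
p.S361L	IBD	0.110		0.0370	n.s.	3.17	1.13	8.90
p.S361L	control	0.035
p.R801H	CD	0.036		0.6900	n.s.	2.40	0.35	17.68
p.R801H	UC	0.017		1.0000	n.s.	1.18	0.10	13.08
p.R801H	IBD	0.026		0.8000	n.s.	1.80	0.30	10.90
p.R801H	control	0.014
combined	CD		0.18	n.s.	n.s.	1.77	0.56	5.6
combined	UC		0.37	0.003	0.009	3.73	1.44	9.63
combined	IBD		0.28	0.018	0.054	2.77	1.14	6.75
combined	control		0.10
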