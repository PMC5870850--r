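site_id	chrom	pos	ref_allele	alt_allele
s1	1	100	A	G
s2	1	200	C	T
s3	1	300	G	A
s4	1	400	T	C
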