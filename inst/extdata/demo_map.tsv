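chrom	pos	cM
1	1000000	0
1	41000000	44
1	81000000	88
1	121000000	132
1	161000000	176
2	1000000	0
2	41000000	44
2	81000000	88
2	121000000	132
2	161000000	176
3	1000000	0
3	41000000	44
3	81000000	88
3	121000000	132
3	161000000	176
4	1000000	0
4	41000000	44
4	81000000	88
4	121000000	132
4	161000000	176
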