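snp_id	chrom	pos	allele1	allele2
demo001	1	2e+06	A	A
demo002	1	1.3e+07	C	C
demo003	1	2.4e+07	A	T
demo004	1	3.5e+07	A	C
demo005	1	4.6e+07	A	A
demo006	1	5.7e+07	G	G
demo007	1	6.8e+07	A	G
demo008	1	7.9e+07	G	T
demo009	1	9e+07	G	G
demo010	1	1.01e+08	A	T
demo011	1	1.12e+08	C	C
demo012	1	1.23e+08	G	T
demo013	1	1.34e+08	A	A
demo014	1	1.45e+08	C	C
demo015	1	1.56e+08	C	C
demo016	2	2e+06	T	T
demo017	2	1.3e+07	A	G
demo018	2	2.4e+07	G	T
demo019	2	3.5e+07	A	T
demo020	2	4.6e+07	A	C
demo021	2	5.7e+07	A	A
demo022	2	6.8e+07	A	T
demo023	2	7.9e+07	A	C
demo024	2	9e+07	T	T
demo025	2	1.01e+08	C	T
demo026	2	1.12e+08	C	G
demo027	2	1.23e+08	C	G
demo028	2	1.34e+08	A	C
demo029	2	1.45e+08	T	T
demo030	2	1.56e+08	G	G
demo031	3	2e+06	T	T
demo032	3	1.3e+07	A	C
demo033	3	2.4e+07	C	C
demo034	3	3.5e+07	A	G
demo035	3	4.6e+07	A	T
demo036	3	5.7e+07	G	T
demo037	3	6.8e+07	G	T
demo038	3	7.9e+07	A	A
demo039	3	9e+07	C	C
demo040	3	1.01e+08	A	T
demo041	3	1.12e+08	A	T
demo042	3	1.23e+08	C	C
demo043	3	1.34e+08	A	C
demo044	3	1.45e+08	G	G
demo045	3	1.56e+08	G	G
demo046	4	2e+06	A	G
demo047	4	1.3e+07	A	C
demo048	4	2.4e+07	A	T
demo049	4	3.5e+07	A	A
demo050	4	4.6e+07	A	C
demo051	4	5.7e+07	A	A
demo052	4	6.8e+07	A	A
demo053	4	7.9e+07	A	C
demo054	4	9e+07	A	A
demo055	4	1.01e+08	C	T
demo056	4	1.12e+08	A	G
demo057	4	1.23e+08	C	C
demo058	4	1.34e+08	A	A
demo059	4	1.45e+08	C	G
demo060	4	1.56e+08	A	C
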