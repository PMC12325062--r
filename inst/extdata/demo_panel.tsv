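snp_id	chrom	pos	ref	alt	POP_A	POP_B
demo001	1	2e+06	A	C	0.4004	0.531
demo002	1	1.3e+07	A	C	0.5717	0.6003
demo003	1	2.4e+07	A	T	0.4822	0.4721
demo004	1	3.5e+07	C	A	0.6851	0.7038
demo005	1	4.6e+07	A	T	0.3397	0.3352
demo006	1	5.7e+07	G	A	0.5724	0.5183
demo007	1	6.8e+07	G	A	0.5657	0.5903
demo008	1	7.9e+07	T	G	0.6888	0.728
demo009	1	9e+07	T	G	0.6672	0.6839
demo010	1	1.01e+08	T	A	0.3097	0.3258
demo011	1	1.12e+08	A	C	0.4966	0.5045
demo012	1	1.23e+08	G	T	0.4071	0.4486
demo013	1	1.34e+08	T	A	0.5492	0.4852
demo014	1	1.45e+08	C	T	0.5522	0.6086
demo015	1	1.56e+08	C	A	0.3731	0.3317
demo016	2	2e+06	T	C	0.4394	0.456
demo017	2	1.3e+07	G	A	0.4568	0.4954
demo018	2	2.4e+07	G	T	0.3054	0.3155
demo019	2	3.5e+07	A	T	0.3248	0.2604
demo020	2	4.6e+07	C	A	0.5989	0.6001
demo021	2	5.7e+07	A	G	0.4869	0.5036
demo022	2	6.8e+07	T	A	0.6774	0.7191
demo023	2	7.9e+07	C	A	0.3248	0.3471
demo024	2	9e+07	C	T	0.6243	0.6509
demo025	2	1.01e+08	C	T	0.688	0.7349
demo026	2	1.12e+08	C	G	0.3897	0.3566
demo027	2	1.23e+08	C	G	0.3956	0.3664
demo028	2	1.34e+08	A	C	0.3197	0.3193
demo029	2	1.45e+08	A	T	0.4604	0.4773
demo030	2	1.56e+08	T	G	0.4454	0.5154
demo031	3	2e+06	T	A	0.3991	0.3584
demo032	3	1.3e+07	A	C	0.4568	0.4139
demo033	3	2.4e+07	T	C	0.6553	0.6894
demo034	3	3.5e+07	G	A	0.5858	0.5662
demo035	3	4.6e+07	T	A	0.524	0.5132
demo036	3	5.7e+07	G	T	0.488	0.5183
demo037	3	6.8e+07	G	T	0.4984	0.4677
demo038	3	7.9e+07	C	A	0.595	0.5597
demo039	3	9e+07	A	C	0.695	0.684
demo040	3	1.01e+08	T	A	0.6458	0.6277
demo041	3	1.12e+08	T	A	0.5141	0.4797
demo042	3	1.23e+08	C	A	0.5741	0.6162
demo043	3	1.34e+08	C	A	0.6365	0.614
demo044	3	1.45e+08	A	G	0.6476	0.6507
demo045	3	1.56e+08	T	G	0.5327	0.5395
demo046	4	2e+06	A	G	0.3286	0.2523
demo047	4	1.3e+07	A	C	0.3068	0.3217
demo048	4	2.4e+07	A	T	0.3822	0.4552
demo049	4	3.5e+07	T	A	0.6206	0.6199
demo050	4	4.6e+07	A	C	0.32	0.2872
demo051	4	5.7e+07	A	T	0.3338	0.3944
demo052	4	6.8e+07	A	G	0.5171	0.5301
demo053	4	7.9e+07	C	A	0.3624	0.4104
demo054	4	9e+07	A	G	0.3609	0.3709
demo055	4	1.01e+08	T	C	0.6719	0.6983
demo056	4	1.12e+08	G	A	0.5897	0.6574
demo057	4	1.23e+08	G	C	0.5712	0.6031
demo058	4	1.34e+08	T	A	0.6613	0.6779
demo059	4	1.45e+08	C	G	0.4776	0.4441
demo060	4	1.56e+08	C	A	0.5739	0.602
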