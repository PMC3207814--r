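rank	printed_fold	focal_76	focal_39	ref_76	ref_39	gene
1	290.4	37073	596	27	4	Epcam
2	252.9	31261	1075	23	14	Suclg2
3	207.7	25654	926	23	1	Gulp1
4	189.8	31590	1166	66	3	Acmsd
5	183.1	19309	339	5	8	Eif4g1
6	169.9	18421	4336	8	0	Tyro3
7	154.2	19335	2868	25	21	Upb1
8	146.5	14695	903	0	0	Tspan1
9	143.9	202485	14461	1307	0	A2m
10	135.8	21227	981	56	168	Ugt1a10
11	131.4	14613	2961	11	7	Scd3
12	123.6	12512	4230	1	0	Rpl39l
13	122.5	74402	3182	507	144	Rpl26
14	112.5	21058	7205	87	358	Fau
15	107.7	11959	721	11	7	Amacr
16	104.6	19454	5099	86	4	Crym
17	95.7	11671	1140	22	6	Upp2
18	90.8	9523	1438	5	0	Moxd1
19	90.5	16106	3522	78	12	Mt2
20	88.3	13769	1218	56	56	Sdc2
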