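cluster	size	phi1	sd_phi1	psi1	sd_psi1	phi2	sd_phi2	psi2	sd_psi2	phi3	sd_phi3	psi3	sd_psi3	chi1_cys	sd_chi1_cys	chi1_his	sd_chi1_his
1	86	-59	5	-37	8	-65	7	-47	12	-79	18	-21	19	72	4	-75	8
2	16	-63	6	-26	11	-91	13	-34	12	-116	12	10	32	177	6	-61	6
3	13	-63	3	-31	10	-79	3	-41	3	-116	7	-6	2	67	3	-53	4
4	11	-62	8	-40	11	-83	9	-33	13	-119	12	78	9	-178	3	-51	6
5	1	-86	0	-3	0	-110	0	-24	0	-135	0	158	0	-175	0	93	0
6	1	-58	0	-48	0	-59	0	-54	0	-63	0	-45	0	-177	0	-81	0
7	1	-121	0	-37	0	-57	0	-30	0	-115	0	18	0	178	0	-50	0
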