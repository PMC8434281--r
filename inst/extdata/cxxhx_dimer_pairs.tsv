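entry	cluster	seq_a	start_a	chi1_cys_a	chi1_pos4_a	seq_b	start_b	chi1_cys_b	chi1_pos4_b
2v0c_A	4	CWRHE	176	174	-59	CPKCQ	159	177	-65
4ijd_A	2	CAAHG	216	174	-62	CEMCQ	205	179	-61
4ijd_B	2	CAAHG	216	-176	-56	CEMCQ	205	177	-57
2au3_A	5	CPFHP	35	-175	93	CFGCG	56	-172	67
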