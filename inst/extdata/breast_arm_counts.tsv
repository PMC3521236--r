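pre_mirna	n5p	n3p	t5p	t3p
hsa-miR-214	88	226	133	171
hsa-miR-576	7	44	19	17
hsa-miR-154	21	8	7	14
hsa-miR-193a	1836	1127	488	2384
hsa-miR-296	24	34	8	4
hsa-miR-361	105	215	1043	310
hsa-miR-324	233	341	317	91
hsa-miR-339	215	217	298	194
hsa-miR-493	2	5	22	9
hsa-miR-455	99	72	107	308
hsa-miR-664	58	8	21	87
hsa-miR-212	22	7	7	6
hsa-miR-142	914	1102	8661	10074
hsa-miR-362	174	34	145	114
hsa-miR-376a-1	41	24	9	13
hsa-miR-382	217	23	51	30
hsa-miR-151	946	1249	2721	3109
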