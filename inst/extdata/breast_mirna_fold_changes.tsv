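mirna	tpm_normal	tpm_tumor	ngs_fc	pcr_fc	consistent
has-let-7b	32594.1	16107.1	0.49	0.46	Y
hsa-let-7c	7710.1	2439.1	0.32	0.44	Y
hsa-miR-22	69532.1	24576.1	0.35	0.24	Y
hsa-miR-125b	44624.1	6613.1	0.15	0.37	Y
hsa-miR-143	38419.1	17359.1	0.45	0.14	Y
hsa-miR-144	3548.1	351.1	0.10	0.30	Y
hsa-miR-145	28682.1	6435.1	0.22	0.26	Y
hsa-miR-193a-5p	1836.1	298.1	0.16	0.27	Y
hsa-miR-193b	2469.1	1058.1	0.43	0.30	Y
hsa-miR-199b-5p	1608.1	1055.1	0.66	0.83	Y
hsa-miR-320a	16734.1	3060.1	0.18	0.75	Y
hsa-miR-378	12610.1	1542.1	0.12	0.24	Y
hsa-miR-497	8005.1	2010.1	0.25	0.29	Y
hsa-miR-99a	31360.1	5548.1	0.18	0.16	Y
hsa-miR-141	5007.1	14541.1	2.90	5.88	Y
hsa-miR-375	240.1	2372.1	9.88	37.95	Y
hsa-miR-425	592.1	2529.1	4.27	1.93	Y
hsa-miR-203	197.1	1045.1	5.30	9.80	Y
hsa-miR-342-3p	350.1	1331.1	3.80	3.43	Y
hsa-miR-182	316.1	1653.1	5.23	11.86	Y
hsa-miR-200b	1362.1	4162.1	3.06	12.61	Y
hsa-miR-183	118.1	1067.1	9.04	6.12	Y
hsa-miR-423-3p	2446.1	1993.1	0.81	5.96	N
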