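dataset	sensitivity.HiLo	sensitivity.Mix	fpra.HiLo	fpra.Mix	diversity.HiLo	diversity.Mix	similarity.HiLo	similarity.Mix	similarity_gcn.HiLo	similarity_gcn.Mix
Actual	100	100	0	0	16	16	100	100	100	100
Lab 2	100	100	0.65	0.5	18	18	61	78	68	72
Lab 3	81	88	1.91	11.08	17	24	43	60	49	53
Lab 4	94	94	0.13	3.4	21	20	71	80	72	69
Lab 5	94	94	0.12	4.1	16	16	64	73	66	61
Lab 6-P	100	100	0.64	3.38	37	53	38	68	42	63
Lab 6-S	100	100	0.66	3.46	39	56	38	68	43	63
Lab 7	100	100	0.05	9.42	26	45	55	64	59	55
Lab 8-H	88	88	1.29	6.39	17	15	66	77	74	71
Lab 8-R	94	94	0.1	3.04	16	16	67	81	74	72
Lab 9	100	100	0.01	0.01	23	22	60	80	67	73
Lab 11	94	94	0	0	19	21	65	80	71	74
Lab 12	88	88	0.21	10.51	18	23	47	62	41	57
Lab 13	94	94	0.16	3.33	16	16	68	79	65	67
Lab 14	94	94	0.12	2.73	16	16	63	73	69	67
Lab 16	100	100	0.02	0.03	21	26	58	76	66	69
Lab 17	100	100	0.02	0.01	30	25	66	80	72	71
Lab 18	94	94	0.03	0	22	17	56	77	68	67
Lab 20	100	100	0.36	4.07	28	28	58	74	62	65
Lab 21	100	100	1.48	4.14	157	161	63	77	70	72
Lab 22	94	94	0.02	1.59	16	16	55	64	48	59
Lab 23	94	94	0.17	2.59	16	16	60	74	61	61
Lab 24-V3-V4	88	94	0	0.01	15	17	55	64	48	55
Lab 24-V4	88	88	0	0	14	14	71	71	59	60
MQC	>=94	>=94	<=0.50	<=4.09	16	16	>=55	>=68	>=54	>=61
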