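dataset	sensitivity.HiLo	sensitivity.Mix	fpra.HiLo	fpra.Mix	diversity.HiLo	diversity.Mix	similarity.HiLo	similarity.Mix
Actual	100	100	0	0	19	19	100	100
Lab 2	68	89	0	0	13	17	90	84
Lab 4	95	95	8.06	2.57	21	23	80	82
Lab 5-H	74	74	0	0	14	14	71	68
Lab 5-R	63	89	0	0	12	17	83	80
Lab 6	95	95	13.36	3.25	19	19	60	71
Lab 8	95	95	0	0	18	18	78	72
Lab 10	74	95	0	0	14	18	87	84
Lab 11	100	100	1.06	2.84	170	180	69	68
Lab 13	68	95	0	0	13	18	85	83
Lab 14	63	95	0	0	12	18	95	86
Lab 15-MiSeq	63	95	0	0	12	18	88	84
Lab 15-NS2000	68	95	0	0	13	18	89	81
Lab 15-NS550	63	95	0	0	12	18	83	85
Lab 16	95	95	7.29	40.82	185	154	55	34
Lab 18	95	95	0	0	19	19	88	85
Lab 19	95	95	0	0	19	21	91	86
Lab 21	84	84	2.11	4.46	71	112	72	71
Lab 22	95	95	0	0	18	19	77	77
Lab 24	95	95	0	0	19	19	90	87
MQC	>=68	>=95	<=0.53	<=1.29	13-19	18-19	>=75	>=72
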