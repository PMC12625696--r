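dataset	sensitivity.HiLo	sensitivity.Mix	fpra.HiLo	fpra.Mix	diversity.HiLo	diversity.Mix	similarity.HiLo	similarity.Mix
Lab 2	1	0	1	1	1	0	1	1
Lab 4	1	1	0	0	0	0	1	1
Lab 5-H	1	0	1	1	1	0	0	0
Lab 5-R	0	0	1	1	0	0	1	1
Lab 6	1	1	0	0	1	1	0	0
Lab 8	1	1	1	1	1	1	1	1
Lab 10	1	1	1	1	1	1	1	1
Lab 11	1	1	0	0	0	0	0	0
Lab 13	1	1	1	1	1	1	1	1
Lab 14	0	1	1	1	0	1	1	1
Lab 15-MiSeq	0	1	1	1	0	1	1	1
Lab 15-NS2000	1	1	1	1	1	1	1	1
Lab 15-NS550	0	1	1	1	0	1	1	1
Lab 16	1	1	0	0	0	0	0	0
Lab 18	1	1	1	1	1	1	1	1
Lab 19	1	1	1	1	1	0	1	1
Lab 21	1	0	0	0	0	0	0	0
Lab 22	1	1	1	1	1	1	1	1
Lab 24	1	1	1	1	1	1	1	1
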