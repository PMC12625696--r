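dataset	sensitivity.HiLo	sensitivity.Mix	fpra.HiLo	fpra.Mix	diversity.HiLo	diversity.Mix	similarity.HiLo	similarity.Mix	similarity_gcn.HiLo	similarity_gcn.Mix
Lab 2	1	1	0	1	0	0	1	1	1	1
Lab 3	0	0	0	0	0	0	0	0	0	0
Lab 4	1	1	1	1	0	0	1	1	1	1
Lab 5	1	1	1	0	1	1	1	1	1	1
Lab 6-P	1	1	0	1	0	0	0	1	0	1
Lab 6-S	1	1	0	1	0	0	0	1	0	1
Lab 7	1	1	1	0	0	0	1	0	1	0
Lab 8-H	0	0	0	0	0	0	1	1	1	1
Lab 8-R	1	1	1	1	1	1	1	1	1	1
Lab 9	1	1	1	1	0	0	1	1	1	1
Lab 11	1	1	1	1	0	0	1	1	1	1
Lab 12	0	0	1	0	0	0	0	0	0	0
Lab 13	1	1	1	1	1	1	1	1	1	1
Lab 14	1	1	1	1	1	1	1	1	1	1
Lab 16	1	1	1	1	0	0	1	1	1	1
Lab 17	1	1	1	1	0	0	1	1	1	1
Lab 18	1	1	1	1	0	0	1	1	1	1
Lab 20	1	1	1	1	0	0	1	1	1	1
Lab 21	1	1	0	0	0	0	1	1	1	1
Lab 22	1	1	1	1	1	1	1	0	0	0
Lab 23	1	1	1	1	1	1	1	1	1	1
Lab 24-V3-V4	0	1	1	1	0	0	1	0	0	0
Lab 24-V4	0	0	1	1	0	0	1	1	1	0
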