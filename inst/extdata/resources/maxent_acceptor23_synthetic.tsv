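submodel	positions	sign	kmer	prob
pos01	1	1	A	0.1151
pos01	1	1	C	0.3445
pos01	1	1	G	0.0958
pos01	1	1	T	0.4446
pos02	2	1	A	0.1028
pos02	2	1	C	0.3093
pos02	2	1	G	0.1332
pos02	2	1	T	0.4548
pos03	3	1	A	0.1275
pos03	3	1	C	0.3096
pos03	3	1	G	0.1105
pos03	3	1	T	0.4524
pos04	4	1	A	0.0888
pos04	4	1	C	0.3466
pos04	4	1	G	0.1316
pos04	4	1	T	0.4329
pos05	5	1	A	0.1349
pos05	5	1	C	0.3295
pos05	5	1	G	0.1337
pos05	5	1	T	0.4019
pos06	6	1	A	0.1047
pos06	6	1	C	0.3314
pos06	6	1	G	0.1031
pos06	6	1	T	0.4607
pos07	7	1	A	0.0940
pos07	7	1	C	0.3434
pos07	7	1	G	0.1120
pos07	7	1	T	0.4505
pos08	8	1	A	0.0993
pos08	8	1	C	0.3490
pos08	8	1	G	0.1037
pos08	8	1	T	0.4479
pos09	9	1	A	0.1219
pos09	9	1	C	0.3195
pos09	9	1	G	0.1240
pos09	9	1	T	0.4346
pos10	10	1	A	0.1098
pos10	10	1	C	0.3439
pos10	10	1	G	0.0933
pos10	10	1	T	0.4529
pos11	11	1	A	0.1281
pos11	11	1	C	0.3486
pos11	11	1	G	0.1043
pos11	11	1	T	0.4189
pos12	12	1	A	0.0929
pos12	12	1	C	0.3512
pos12	12	1	G	0.1015
pos12	12	1	T	0.4544
pos13	13	1	A	0.1230
pos13	13	1	C	0.3313
pos13	13	1	G	0.1272
pos13	13	1	T	0.4185
pos14	14	1	A	0.0952
pos14	14	1	C	0.3282
pos14	14	1	G	0.1145
pos14	14	1	T	0.4621
pos15	15	1	A	0.1295
pos15	15	1	C	0.3509
pos15	15	1	G	0.1103
pos15	15	1	T	0.4093
pos16	16	1	A	0.1460
pos16	16	1	C	0.3459
pos16	16	1	G	0.1109
pos16	16	1	T	0.3971
pos17	17	1	A	0.0942
pos17	17	1	C	0.3355
pos17	17	1	G	0.1468
pos17	17	1	T	0.4235
pos18	18	1	A	0.2200
pos18	18	1	C	0.6199
pos18	18	1	G	0.0401
pos18	18	1	T	0.1201
pos19	19	1	A	0.9697
pos19	19	1	C	0.0101
pos19	19	1	G	0.0101
pos19	19	1	T	0.0101
pos20	20	1	A	0.0101
pos20	20	1	C	0.0101
pos20	20	1	G	0.9697
pos20	20	1	T	0.0101
pos21	21	1	A	0.2500
pos21	21	1	C	0.1400
pos21	21	1	G	0.5199
pos21	21	1	T	0.0901
pos22	22	1	A	0.2733
pos22	22	1	C	0.2206
pos22	22	1	G	0.2671
pos22	22	1	T	0.2390
pos23	23	1	A	0.2659
pos23	23	1	C	0.2575
pos23	23	1	G	0.2377
pos23	23	1	T	0.2388
background			A	0.2500
background			C	0.2500
background			G	0.2500
background			T	0.2500
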