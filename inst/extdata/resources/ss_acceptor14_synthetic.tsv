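position	A	C	G	T
1	0.0993	0.3491	0.1037	0.4480
2	0.1218	0.3195	0.1239	0.4347
3	0.1098	0.3440	0.0932	0.4530
4	0.1281	0.3487	0.1043	0.4190
5	0.0928	0.3513	0.1015	0.4544
6	0.1229	0.3314	0.1272	0.4185
7	0.0951	0.3282	0.1144	0.4622
8	0.1294	0.3510	0.1102	0.4094
9	0.1460	0.3460	0.1109	0.3972
10	0.0942	0.3355	0.1468	0.4236
11	0.2200	0.6200	0.0400	0.1200
12	0.9700	0.0100	0.0100	0.0100
13	0.0100	0.0100	0.9700	0.0100
14	0.2500	0.1400	0.5200	0.0900
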