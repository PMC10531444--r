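submodel	positions	sign	kmer	prob
pos01	1	1	A	0.3263
pos01	1	1	C	0.3596
pos01	1	1	G	0.1896
pos01	1	1	T	0.1245
pos02	2	1	A	0.5929
pos02	2	1	C	0.1324
pos02	2	1	G	0.1422
pos02	2	1	T	0.1324
pos03	3	1	A	0.0933
pos03	3	1	C	0.0541
pos03	3	1	G	0.7692
pos03	3	1	T	0.0835
pos04	4	1	A	0.0100
pos04	4	1	C	0.0100
pos04	4	1	G	0.9700
pos04	4	1	T	0.0100
pos05	5	1	A	0.0100
pos05	5	1	C	0.0149
pos05	5	1	G	0.0100
pos05	5	1	T	0.9651
pos06	6	1	A	0.5929
pos06	6	1	C	0.0737
pos06	6	1	G	0.2598
pos06	6	1	T	0.0737
pos07	7	1	A	0.6908
pos07	7	1	C	0.0835
pos07	7	1	G	0.1227
pos07	7	1	T	0.1031
pos08	8	1	A	0.0835
pos08	8	1	C	0.0639
pos08	8	1	G	0.7888
pos08	8	1	T	0.0639
pos09	9	1	A	0.1716
pos09	9	1	C	0.1520
pos09	9	1	G	0.1912
pos09	9	1	T	0.4851
background			A	0.2500
background			C	0.2500
background			G	0.2500
background			T	0.2500
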