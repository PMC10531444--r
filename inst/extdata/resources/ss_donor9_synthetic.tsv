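position	A	C	G	T
1	0.3279	0.3619	0.1884	0.1218
2	0.6000	0.1300	0.1400	0.1300
3	0.0900	0.0500	0.7800	0.0800
4	0.0050	0.0050	0.9850	0.0050
5	0.0050	0.0100	0.0050	0.9800
6	0.6000	0.0700	0.2600	0.0700
7	0.7000	0.0800	0.1200	0.1000
8	0.0800	0.0600	0.8000	0.0600
9	0.1700	0.1500	0.1900	0.4900
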