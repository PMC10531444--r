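position	A	C	G	T
1	0.0800	0.3600	0.1100	0.4500
2	0.0300	0.0400	0.0300	0.9000
3	0.3000	0.2500	0.2000	0.2500
4	0.9400	0.0200	0.0200	0.0200
5	0.1000	0.4000	0.1500	0.3500
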