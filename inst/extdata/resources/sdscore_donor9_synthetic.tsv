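position	A	C	G	T
1	0.3255	0.3624	0.1914	0.1207
2	0.5989	0.1288	0.1399	0.1324
3	0.0982	0.0512	0.7700	0.0806
4	0.0123	0.0115	0.9691	0.0070
5	0.0136	0.0139	0.0062	0.9663
6	0.5933	0.0764	0.2577	0.0726
7	0.6952	0.0789	0.1250	0.1009
8	0.0849	0.0673	0.7841	0.0637
9	0.1711	0.1540	0.1930	0.4818
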