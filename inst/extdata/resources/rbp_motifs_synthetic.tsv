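rbp	motif	score
SRSF1	GAAGAA	6
SRSF1	GARGAR	3
SRSF2	GARGAR	3
SRSF3	CRSMSGW	4
SRSF3	ACGAGAGAY	3
SRSF4	ACGAGAGAY	4
SRSF5	WGGACRA	4
SRSF5	GGUCCUCUUC	2
SRSF6	GGUCCUCUUC	4
SRSF7	AGGACRRAGC	3
SRSF7	GAAGGA	6
SRSF9	GAAGGA	5
SRSF10	GCUCCUCUUCC	2
SRSF10	AAGAAGAAGAA	6
SRSF11	AAGAAGAAGAA	6
SRSF12	GAAGAA	2
SRSF12	GARGAR	5
Tra2alpha	GHVVGANR	5
Tra2beta	GAAARGARR	2
Tra2beta	AGAA	2
hnRNP A1	UAGACU	-4
hnRNP A2/B1	UAGGGU	-5
hnRNP A2/B1	UAGGGW	-4
hnRNP C	UUUUUUU	-5
hnRNP D	UUAGG	-3
hnRNP D	AUUUA	-6
hnRNP E1	UCCCU	-4
hnRNP E2	CCCUCCC	-6
hnRNP E2	UCCCU	-2
hnRNP F	GGGG	-5
hnRNP G	AAGU	4
hnRNP G	CCAY	4
hnRNP H1	GGGA	-4
hnRNP H2	GGGG	-5
hnRNP H2	GGGAGG	-4
hnRNP H3	GGGAGG	-4
hnRNP K	UCCCGCA	-6
hnRNP K	CCCC	-3
hnRNP L	CACACA	-6
hnRNP LL	ACACA	-6
hnRNP LL	CACACA	-5
hnRNP M	UGGUG	-2
hnRNP Q	UAUUAU	-2
hnRNP Q	AUAAU	-4
hnRNP U	GGUUG	-3
PTB	CUCUCU	-4
PTB	UUCUCU	-5
nPTB	UUCUCU	-3
ETR-3	UGUU	2
ETR-3	GUGUU	4
CUG-BP1	GUGUU	6
CELF3	UGUGUU	5
CELF3	UGUUGU	5
CELF4	UGUUGU	2
CELF5	UGUU	5
CELF5	GUGUU	5
CELF6	GUGUU	3
MBNL1	CGCUU	-2
MBNL1	YGCUUY	-3
NOVA-1	UCAUY	5
NOVA-2	YCAY	6
NOVA-2	UCAUY	3
Fox-1	GCAUG	3
Fox-2	UGCAUG	2
Fox-2	GCAUG	6
HuB	AUUUA	-4
HuC	UUUGUUU	-6
HuC	UUUAUUU	-6
HuD	UUUAUUU	-4
HuR	AUUUA	-2
HuR	UUUGUUU	-4
TIA-1	UUCUUUU	-2
TIAR	UUUUUAU	-2
TIAR	UUCUUUU	-5
KSRP	UGUUU	4
Sam68	ACUAAY	-6
Sam68	UAAA	-2
SLM-1	UAAA	-4
SLM-2	UUAAA	-6
SLM-2	ACUAAY	-6
QKI	UAAC	-4
YB-1	CAUC	4
YB-1	AACAUC	2
SF1	UAACUAAC	5
U2AF65	YAGG	4
U2AF65	UUUUUYC	3
U2AF35	UUUUUYC	4
ESRP1	UGGGGAU	2
ESRP1	GGUGG	3
ESRP2	GGUGG	4
RBM4	GACGAC	2
RBM4	CGCG	2
RBM5	CGCG	6
RBM25	GAAGGAA	2
RBM25	GACGAC	3
SRp38	ACGAGAGAY	4
ZRANB2	GUAGUA	3
ZRANB2	AGGUAA	2
MBNL2	CGCUU	-4
DAZAP1	UAGGGW	-6
DAZAP1	UAGACU	-5
PSF	GGUAAG	2
p54nrb	GUAGUA	2
p54nrb	AGGUAA	6
TDP43	AUAAU	-6
FUS	UGUGUG	2
FUS	GGUAAG	4
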