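variant	gene	coordinate	ref	obs	het_cases	het_controls	wt_cases	wt_controls	protein
RAB11FIP5_P652H	RAB11FIP5	chr2:73302656	G	T	1	0	1540	5785	P652H
ABP1_R345P	ABP1	chr7:150554592	G	C	1	0	1540	5785	R345P
JMJD7-PLA2G4B_splice	JMJD7-PLA2G4B	chr15:42133295	T	A	1	0	1540	5785	NA
C7orf10_R288W	C7orf10	chr7:40498796	C	T	28	65	1513	5720	R288W
AKAP9_R3233C	AKAP9	chr7:91724455	C	T	4	4	1537	5781	R3233C
HEPACAM2_G398R	HEPACAM2	chr7:92825188	C	T	17	35	1524	5750	G398R
ALX1_R64L	ALX1	chr12:85674230	G	T	27	58	1514	5727	R64L
AP1G2_R99C	AP1G2	chr14:24035159	G	A	12	27	1529	5757	R99C
CLMN_P158A	CLMN	chr14:95679692	G	C	8	18	1533	5767	P158A
MOK_Q22X	MOK	chr14:102749873	G	A	2	2	1539	5783	Q22X
OIP5_S165F	OIP5	chr15:41611874	G	A	3	5	1538	5780	S165F
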