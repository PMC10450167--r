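# Idealized nucleotide monomer coordinates (heavy atoms, Angstrom),
# standard chemical-component reference geometry.
res	atom	element	x	y	z
A	P	P	1.0240	-0.1370	-4.7230
A	OP1	O	1.6330	1.1900	-4.4880
A	OP2	O	-0.1830	0.0050	-5.7780
A	O5'	O	0.4560	-0.7200	-3.3340
A	C5'	C	-0.5200	0.2090	-2.8630
A	C4'	C	-1.1010	-0.2870	-1.5380
A	O4'	O	-0.0640	-0.3830	-0.5380
A	C3'	C	-2.1050	0.7390	-0.9690
A	O3'	O	-3.4450	0.3600	-1.2870
A	C2'	C	-1.8740	0.6840	0.5580
A	O2'	O	-3.0650	0.2710	1.2310
A	C1'	C	-0.7550	-0.3670	0.7290
A	N9	N	0.1580	0.0290	1.8030
A	C8	C	1.2650	0.8130	1.6720
A	N7	N	1.8430	0.9630	2.8280
A	C5	C	1.1430	0.2920	3.7730
A	C6	C	1.2900	0.0910	5.1560
A	N6	N	2.3440	0.6640	5.8460
A	N1	N	0.3910	-0.6560	5.7870
A	C2	C	-0.6170	-1.2060	5.1360
A	N3	N	-0.7920	-1.0510	3.8410
A	C4	C	0.0560	-0.3200	3.1260
G	P	P	-0.9110	-0.2770	5.0080
G	OP1	O	-1.5980	1.0220	4.8440
G	OP2	O	0.3250	-0.1050	6.0250
G	O5'	O	-0.3650	-0.7800	3.5800
G	C5'	C	0.5420	0.2170	3.1090
G	C4'	C	1.1000	-0.2000	1.7480
G	O4'	O	0.0330	-0.3180	0.7820
G	C3'	C	2.0250	0.8980	1.1820
G	O3'	O	3.3950	0.5820	1.4390
G	C2'	C	1.7410	0.8840	-0.3380
G	O2'	O	2.9270	0.5600	-1.0660
G	C1'	C	0.6750	-0.2200	-0.5070
G	N9	N	-0.2970	0.1620	-1.5340
G	C8	C	-1.4400	0.8800	-1.3340
G	N7	N	-2.0660	1.0370	-2.4640
G	C5	C	-1.3640	0.4310	-3.4530
G	C6	C	-1.5560	0.2790	-4.8460
G	O6	O	-2.5340	0.7550	-5.3970
G	N1	N	-0.6260	-0.4010	-5.5510
G	C2	C	0.4590	-0.9340	-4.9230
G	N2	N	1.3840	-1.6260	-5.6640
G	N3	N	0.6490	-0.8000	-3.6300
G	C4	C	-0.2260	-0.1340	-2.8680
C	P	P	1.0490	-0.0390	-4.0280
C	OP1	O	1.6920	1.2370	-3.6460
C	OP2	O	-0.1160	0.2460	-5.1020
C	O5'	O	0.4150	-0.7330	-2.7210
C	C5'	C	-0.5460	0.1810	-2.1930
C	C4'	C	-1.1890	-0.4190	-0.9420
C	O4'	O	-0.1900	-0.6480	0.0760
C	C3'	C	-2.1780	0.5830	-0.3070
C	O3'	O	-3.5180	0.2830	-0.7030
C	C2'	C	-2.0010	0.3730	1.2150
C	O2'	O	-3.2280	-0.0590	1.8060
C	C1'	C	-0.9240	-0.7290	1.3170
C	N1	N	-0.0360	-0.4700	2.4530
C	C2	C	0.6520	0.6830	2.5140
C	O2	O	0.5290	1.5040	1.6200
C	N3	N	1.4670	0.9450	3.5350
C	C4	C	1.6200	0.0700	4.5200
C	N4	N	2.4640	0.3500	5.5690
C	C5	C	0.9160	-1.1510	4.4830
C	C6	C	0.0870	-1.3990	3.4420
U	P	P	-1.0300	0.0470	-4.0370
U	OP1	O	-1.6790	-1.2280	-3.6600
U	OP2	O	0.1380	-0.2410	-5.1070
U	O5'	O	-0.3990	0.7360	-2.7260
U	C5'	C	0.5570	-0.1820	-2.1960
U	C4'	C	1.1970	0.4150	-0.9420
U	O4'	O	0.1940	0.6450	0.0740
U	C3'	C	2.1810	-0.5880	-0.3010
U	O3'	O	3.5240	-0.2880	-0.6860
U	C2'	C	1.9950	-0.3830	1.2180
U	O2'	O	3.2190	0.0460	1.8190
U	C1'	C	0.9220	0.7230	1.3190
U	N1	N	0.0280	0.4640	2.4510
U	C2	C	-0.6900	-0.6710	2.4860
U	O2	O	-0.5870	-1.4740	1.5800
U	N3	N	-1.5150	-0.9360	3.5170
U	C4	C	-1.6410	-0.0550	4.5300
U	O4	O	-2.3910	-0.2920	5.4600
U	C5	C	-0.8940	1.1460	4.5020
U	C6	C	-0.0700	1.3840	3.4590
DA	P	P	0.9340	-0.1560	-4.6360
DA	OP1	O	1.7810	0.9960	-4.2550
DA	OP2	O	-0.2040	0.3310	-5.6650
DA	O5'	O	0.2410	-0.7710	-3.3200
DA	C5'	C	-0.5490	0.2700	-2.7440
DA	C4'	C	-1.2390	-0.2510	-1.4820
DA	O4'	O	-0.2670	-0.5640	-0.4580
DA	C3'	C	-2.1050	0.8590	-0.8350
DA	O3'	O	-3.4090	0.8950	-1.4180
DA	C2'	C	-2.1730	0.3980	0.6400
DA	C1'	C	-0.9650	-0.5450	0.7970
DA	N9	N	-0.0780	-0.0470	1.8520
DA	C8	C	0.9620	0.8170	1.6890
DA	N7	N	1.5350	1.0440	2.8350
DA	C5	C	0.8970	0.3460	3.8050
DA	C6	C	1.0690	0.1960	5.1910
DA	N6	N	2.0790	0.8690	5.8560
DA	N1	N	0.2360	-0.6030	5.8500
DA	C2	C	-0.7290	-1.2490	5.2240
DA	N3	N	-0.9250	-1.1440	3.9270
DA	C4	C	-0.1420	-0.3680	3.1840
DG	P	P	-0.8180	-0.3210	4.9350
DG	OP1	O	-1.7740	0.7660	4.6300
DG	OP2	O	0.3120	0.2240	5.9410
DG	O5'	O	-0.1260	-0.8260	3.5720
DG	C5'	C	0.5500	0.3000	3.0110
DG	C4'	C	1.2330	-0.1130	1.7060
DG	O4'	O	0.2530	-0.4710	0.7050
DG	C3'	C	1.9760	1.0910	1.0730
DG	O3'	O	3.2940	1.2180	1.6120
DG	C2'	C	2.0260	0.6920	-0.4210
DG	C1'	C	0.8970	-0.3450	-0.5730
DG	N9	N	-0.0680	0.1110	-1.5750
DG	C8	C	-1.1720	0.8770	-1.3410
DG	N7	N	-1.8040	1.0940	-2.4580
DG	C5	C	-1.1450	0.4820	-3.4720
DG	C6	C	-1.3610	0.3770	-4.8660
DG	O6	O	-2.3210	0.9140	-5.3910
DG	N1	N	-0.4730	-0.3270	-5.6010
DG	C2	C	0.5930	-0.9280	-5.0030
DG	N2	N	1.4740	-1.6430	-5.7740
DG	N3	N	0.8040	-0.8390	-3.7090
DG	C4	C	-0.0270	-0.1520	-2.9170
DC	P	P	0.9870	-0.0170	-3.8940
DC	OP1	O	1.8020	1.0990	-3.3650
DC	OP2	O	-0.1190	0.5600	-4.9100
DC	O5'	O	0.2550	-0.7720	-2.6740
DC	C5'	C	-0.5710	0.1960	-2.0270
DC	C4'	C	-1.3000	-0.4590	-0.8520
DC	O4'	O	-0.3630	-0.8630	0.1710
DC	C3'	C	-2.2060	0.5690	-0.1290
DC	O3'	O	-3.4880	0.6490	-0.7560
DC	C2'	C	-2.3220	-0.0400	1.2880
DC	C1'	C	-1.1060	-0.9810	1.3950
DC	N1	N	-0.2670	-0.5840	2.5280
DC	C2	C	0.2700	0.6480	2.5630
DC	O2	O	0.0520	1.4240	1.6470
DC	N3	N	1.0370	1.0350	3.5810
DC	C4	C	1.2910	0.2120	4.5890
DC	N4	N	2.0850	0.6220	5.6350
DC	C5	C	0.7460	-1.0880	4.5800
DC	C6	C	-0.0350	-1.4650	3.5410
DT	P	P	-3.9680	-1.6650	3.1180
DT	OP1	O	-4.4060	-2.5990	4.2080
DT	OP2	O	-4.9010	-0.3600	2.9200
DT	O5'	O	-2.4930	-1.0280	3.3150
DT	C5'	C	-2.0050	-0.1360	2.3270
DT	C4'	C	-0.6110	0.3280	2.7280
DT	O4'	O	0.2470	-0.8290	2.7640
DT	C3'	C	0.0080	1.2860	1.7200
DT	O3'	O	0.9650	2.1210	2.3680
DT	C2'	C	0.7100	0.3600	0.7540
DT	C1'	C	1.1570	-0.7780	1.6570
DT	N1	N	1.1640	-2.0470	0.9890
DT	C2	C	2.3330	-2.5440	0.3740
DT	O2	O	3.4100	-1.9450	0.3630
DT	N3	N	2.1940	-3.7930	-0.2400
DT	C4	C	1.0470	-4.5700	-0.3000
DT	O4	O	0.9950	-5.6630	-0.8570
DT	C5	C	-0.1430	-3.9800	0.3690
DT	C7	C	-1.4200	-4.7570	0.3470
DT	C6	C	-0.0130	-2.7840	0.9580
PSU	N1	N	-0.8700	1.1010	4.5170
PSU	C2	C	-1.5870	-0.0350	4.5670
PSU	N3	N	-1.5100	-0.9460	3.5800
PSU	C4	C	-0.7100	-0.7280	2.5160
PSU	C5	C	0.0530	0.4610	2.4530
PSU	C6	C	-0.0430	1.3570	3.4580
PSU	O2	O	-2.3160	-0.2430	5.5180
PSU	O4	O	-0.6390	-1.5520	1.6210
PSU	C1'	C	0.9590	0.7260	1.2780
PSU	C2'	C	2.0310	-0.3800	1.1650
PSU	O2'	O	3.2610	0.0480	1.7510
PSU	C3'	C	2.1990	-0.5850	-0.3570
PSU	C4'	C	1.2080	0.4180	-0.9860
PSU	O3'	O	3.5370	-0.2860	-0.7580
PSU	O4'	O	0.2170	0.6490	0.0420
PSU	C5'	C	0.5530	-0.1780	-2.2330
PSU	O5'	O	-0.4090	0.7410	-2.7510
PSU	P	P	-1.0560	0.0520	-4.0550
PSU	OP1	O	-1.7010	-1.2220	-3.6700
PSU	OP2	O	-2.1560	1.0390	-4.6940
1MA	P	P	-5.0740	-0.9760	0.0700
1MA	OP1	O	-6.1040	0.0100	-0.3270
1MA	OP2	O	-5.6120	-1.8430	1.3150
1MA	O5'	O	-3.7280	-0.2030	0.4970
1MA	C5'	C	-3.0630	0.7320	-0.3560
1MA	C4'	C	-1.8240	1.2790	0.3540
1MA	O4'	O	-0.8600	0.2280	0.5340
1MA	C3'	C	-1.1600	2.3660	-0.5130
1MA	O3'	O	-1.1270	3.6120	0.1860
1MA	C2'	C	0.2760	1.8390	-0.7490
1MA	O2'	O	1.2310	2.8980	-0.6510
1MA	C1'	C	0.4470	0.8300	0.4150
1MA	N9	N	1.4520	-0.1810	0.0780
1MA	C8	C	1.2190	-1.3800	-0.5360
1MA	N7	N	2.3450	-2.0300	-0.6780
1MA	C5	C	3.3390	-1.2970	-0.1720
1MA	C6	C	4.7920	-1.5080	-0.0450
1MA	N6	N	5.3670	-2.6840	-0.1410
1MA	N1	N	5.4910	-0.3210	0.1890
1MA	CM1	C	6.8740	-0.1690	-0.2710
1MA	C2	C	4.8660	0.6930	0.8520
1MA	N3	N	3.5650	0.8330	0.8920
1MA	C4	C	2.7850	-0.0970	0.3120
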