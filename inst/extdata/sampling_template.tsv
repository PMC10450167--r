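# Guanine monomer used to build the descriptor sampling cloud:
# heavy atoms plus base hydrogens (idealized reference geometry).
res	atom	element	x	y	z
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
G	H8	H	-1.7760	1.2610	-0.3810
G	H1	H	-0.7360	-0.5180	-6.5080
G	H21	H	2.1650	-2.0070	-5.2320
G	H22	H	1.2560	-1.7360	-6.6190
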