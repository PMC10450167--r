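# Anchor atoms (C2', C1', O4') of the cloud's guanine template, local frame.
atom	x	y	z
C2'	-2.002705	0.637284	1.299302
C1'	-1.464731	0.000000	-0.000000
O4'	-1.968042	0.838150	-1.061825
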