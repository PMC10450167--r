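# Calibrated reference-nucleotide placement parameters for the
# idealized duplex generator (see optimize_duplex_placements()).
form	objective	p1	p2	p3	p4	p5	p6	p7	p8	p9	p10	p11	p12	p13	p14
A_RNA	0.05986550	0.83786349825328177	-1.2751037325519028	-1.2008170216886029	-3.3677799686019854	-4.5476285023449075	0.18665618889162938	1.0747630161742596	1.3314553761136974	0.95679352904754567	-4.2241506671489963	-4.1789631176369726	0.59410394317569315	2.6845642562294727	5.0002223479562389
B_DNA	0.05936725	-1.5197058191746489	3.591986078294739	1.8576269213564542	-3.3610580875379235	-4.3087282864436975	-0.22850131756243036	0.59851299188750562	1.2840256044620266	0.68897688017678049	-4.3266193583604027	-3.8146195207875007	-0.19181053980261431	-3.1741148831660655	-0.85808735930836244
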