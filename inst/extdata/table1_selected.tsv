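accession	gene	fc_ra	log2fc_ra	adjp_ra	fc_rapma	log2fc_rapma	adjp_rapma
P21980	TGM2	12.93	3.69	2.97e-06	16.46	4.04	9.78e-07
P29373	CRABP2	10.97	3.46	9.13e-08	5.73	2.52	9.78e-07
Q96CN7	ISOC1	0.2	-2.34	1.26e-06	0.18	-2.51	6.56e-07
P49736	MCM2	0.42	-1.25	1.71e-05	0.4	-1.31	7.41e-06
P06493	CDK1	0.37	-1.45	2.97e-06	0.44	-1.19	1.23e-05
O43602	DCX	0.28	-1.85	2.18e-03	0.24	-2.05	1.10e-03
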