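variant_id	gene	variant_class	missense	sift_class	polyphen_class	regulome_rank	splice_flag	mirna_flag	conservation	reg_potential	ko_mouse	drug_target	brain_expressed
5-HTTLPR	SLC6A4	VNTR	FALSE	na	na	NA	FALSE	FALSE	NA	NA	TRUE	TRUE	TRUE
rs6265	BDNF	SNV	TRUE	tolerated	possibly_damaging	6	FALSE	FALSE	0.9	0.1	TRUE	TRUE	TRUE
rs4680	COMT	SNV	TRUE	tolerated	benign	7	TRUE	FALSE	0.85	0.1	TRUE	TRUE	TRUE
rs1801133	MTHFR	SNV	TRUE	deleterious	probably_damaging	4	FALSE	FALSE	1	0.358	FALSE	FALSE	FALSE
rs2242446	SLC6A2	SNV	FALSE	na	na	2b	FALSE	FALSE	0.3	0.47	TRUE	TRUE	FALSE
rs5443	GNB3	SNV	FALSE	na	na	4	FALSE	FALSE	0.2	0.438	FALSE	TRUE	TRUE
rs1045642	ABCB1	SNV	FALSE	na	na	3a	TRUE	FALSE	0.2	0.1	FALSE	TRUE	FALSE
rs9340799	ESR1	SNV	FALSE	na	na	6	FALSE	FALSE	0.88	0.1	TRUE	TRUE	TRUE
rs6295	HTR1A	SNV	FALSE	na	na	4	FALSE	FALSE	0	0	TRUE	TRUE	TRUE
rs2234693	ESR1	SNV	FALSE	na	na	5	FALSE	FALSE	0.81	0.1	TRUE	TRUE	FALSE
rs4291	ACE	SNV	FALSE	na	na	4	FALSE	FALSE	0.1	0.2	TRUE	TRUE	FALSE
rs242939	CRHR1	SNV	FALSE	na	na	5	FALSE	FALSE	0	0.238	TRUE	TRUE	TRUE
rs6311	HTR2A	SNV	FALSE	na	na	4	FALSE	FALSE	0.3	0.1	TRUE	TRUE	TRUE
rs1360780	FKBP5	SNV	FALSE	na	na	4	FALSE	FALSE	0.2	0.1	TRUE	FALSE	TRUE
rs4713916	FKBP5	SNV	FALSE	na	na	5	FALSE	FALSE	0.1	0.1	TRUE	FALSE	TRUE
rs1800532	TPH1	SNV	FALSE	na	na	5	FALSE	FALSE	0.83	0.1	TRUE	TRUE	TRUE
rs1006737	CACNA1C	SNV	FALSE	na	na	5	FALSE	FALSE	0	0	TRUE	TRUE	TRUE
rs4880	SOD2	SNV	TRUE	tolerated	benign	4	TRUE	FALSE	0	0.22	TRUE	FALSE	FALSE
rs1801131	MTHFR	SNV	TRUE	tolerated	benign	1f	TRUE	FALSE	1	0.4	TRUE	FALSE	FALSE
rs2522833	PCLO	SNV	TRUE	tolerated	benign	7	TRUE	FALSE	0.3	0.1	TRUE	FALSE	FALSE
rs2522833	PCLO	SNV	TRUE	tolerated	benign	7	TRUE	FALSE	0.3	0.1	TRUE	FALSE	FALSE
rs1800629	TNF	SNV	FALSE	na	na	1d	FALSE	FALSE	0.1	0.55	TRUE	FALSE	FALSE
rs4295	ACE	SNV	FALSE	na	na	4	FALSE	FALSE	0.1	0.1	TRUE	FALSE	FALSE
rs4343	ACE	SNV	FALSE	na	na	2b	TRUE	FALSE	0.2	0.62	TRUE	TRUE	FALSE
rs41423247	NR3C1	SNV	FALSE	na	na	2b	FALSE	FALSE	0	0	TRUE	TRUE	FALSE
rs2273289	PLOD1	SNV	FALSE	na	na	2b	FALSE	FALSE	0.3	0.44	FALSE	FALSE	FALSE
rs2715148	PCLO	SNV	FALSE	na	na	5	FALSE	TRUE	0.92	0.1	TRUE	FALSE	FALSE
rs2423618	LINC00687	SNV	FALSE	na	na	5	FALSE	FALSE	0.1	0.1	FALSE	FALSE	FALSE
rs2715147	PCLO	SNV	FALSE	na	na	5	FALSE	FALSE	0.2	0.1	TRUE	FALSE	FALSE
rs9416742	BICC1	SNV	FALSE	na	na	5	FALSE	FALSE	0.1	0.1	TRUE	FALSE	FALSE
rs999845	BICC1	SNV	FALSE	na	na	5	FALSE	FALSE	0.1	0.1	TRUE	FALSE	FALSE
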