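variant_id	gene	variant_class	missense	sift_class	polyphen_class	regulome_rank	splice_flag	mirna_flag	conservation	reg_potential	ko_mouse	drug_target	brain_expressed
rs1801133	MTHFR	SNV	TRUE	deleterious	probably_damaging	4	FALSE	FALSE	1	0.358	FALSE	FALSE	FALSE
rs5443	GNB3	SNV	FALSE	na	na	4	FALSE	FALSE	0.2	0.438	FALSE	TRUE	TRUE
rs242939	CRHR1	SNV	FALSE	na	na	5	FALSE	FALSE	0	0.238	TRUE	TRUE	TRUE
rs1006737	CACNA1C	SNV	FALSE	na	na	5	FALSE	FALSE	0	0	TRUE	TRUE	TRUE
rs4880	SOD2	SNV	TRUE	tolerated	benign	4	TRUE	FALSE	0	0.22	TRUE	FALSE	FALSE
rs6295	HTR1A	SNV	FALSE	na	na	4	FALSE	FALSE	0	0	TRUE	TRUE	TRUE
rs1801131	MTHFR	SNV	TRUE	tolerated	benign	1f	TRUE	FALSE	1	0.4	TRUE	FALSE	FALSE
STin2	SLC6A4	VNTR	FALSE	na	na	4	FALSE	FALSE	NA	NA	TRUE	TRUE	TRUE
rs41423247	NR3C1	SNV	FALSE	na	na	2b	FALSE	FALSE	0	0	TRUE	TRUE	TRUE
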