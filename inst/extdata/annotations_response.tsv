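variant_id	gene	variant_class	missense	sift_class	polyphen_class	regulome_rank	splice_flag	mirna_flag	conservation	reg_potential	ko_mouse	drug_target	brain_expressed
5-HTTLPR	SLC6A4	VNTR	FALSE	na	na	NA	FALSE	FALSE	NA	NA	TRUE	TRUE	TRUE
STin2	SLC6A4	VNTR	FALSE	na	na	4	FALSE	FALSE	NA	NA	TRUE	TRUE	TRUE
rs6265	BDNF	SNV	TRUE	tolerated	possibly_damaging	4	FALSE	FALSE	0.9	0.1	TRUE	TRUE	TRUE
rs7997012	HTR2A	SNV	FALSE	na	na	4	FALSE	FALSE	0.1	0.41	TRUE	TRUE	TRUE
rs6295	HTR1A	SNV	FALSE	na	na	4	FALSE	FALSE	0	0	TRUE	TRUE	TRUE
rs5443	GNB3	SNV	FALSE	na	na	4	FALSE	FALSE	0.2	0.438	TRUE	TRUE	TRUE
rs334558	GSK3B	SNV	FALSE	na	na	5	FALSE	FALSE	0.85	0.1	TRUE	TRUE	FALSE
rs2470890	CYP1A2	SNV	FALSE	na	na	1f	FALSE	FALSE	0.1	0.45	TRUE	TRUE	TRUE
rs6313	HTR2A	SNV	FALSE	na	na	3a	FALSE	FALSE	0.3	0.1	TRUE	TRUE	TRUE
rs2066713	SLC6A4	SNV	FALSE	na	na	5	FALSE	FALSE	0.1	0.1	TRUE	TRUE	TRUE
rs41423247	NR3C1	SNV	FALSE	na	na	2b	FALSE	FALSE	0	0	TRUE	TRUE	TRUE
rs2171363	TPH2	SNV	FALSE	na	na	5	FALSE	FALSE	0.82	0.1	TRUE	TRUE	TRUE
rs2075507	COMT	SNV	FALSE	na	na	4	FALSE	FALSE	0.1	0.1	TRUE	FALSE	FALSE
rs1954787	GRIK4	SNV	FALSE	na	na	5	FALSE	FALSE	0.1	0.1	TRUE	FALSE	FALSE
rs1360780	FKBP5	SNV	FALSE	na	na	4	FALSE	FALSE	0.2	0.1	TRUE	TRUE	TRUE
rs6046805	CFAP61	SNV	FALSE	na	na	6	FALSE	FALSE	0.1	0.1	FALSE	FALSE	FALSE
rs6966038	UBE3C	SNV	FALSE	na	na	7	FALSE	FALSE	0.1	0.1	FALSE	FALSE	FALSE
rs6127921	BMP7	SNV	FALSE	na	na	5	FALSE	FALSE	0.1	0.1	FALSE	FALSE	TRUE
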