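chr2	16080000	16087000	MYCN	0	+
chr4	55095000	55164000	PDGFRA	0	+
chr4	55524000	55606000	KIT	0	+
chr5	1253000	1295000	TERT	0	-
chr7	55086000	55324000	EGFR	0	+
chr7	116312000	116438000	MET	0	+
chr8	38268000	38326000	FGFR1	0	-
chr8	128747000	128753000	MYC	0	+
chr9	21967000	21995000	CDKN2A	0	-
chr9	22002000	22009000	CDKN2B	0	-
chr10	89623000	89728000	PTEN	0	+
chr11	69455000	69469000	CCND1	0	+
chr12	58141000	58149000	CDK4	0	-
chr12	69201000	69239000	MDM2	0	+
chr13	48877000	49056000	RB1	0	+
chr17	7571000	7590000	TP53	0	-
chr17	29421000	29709000	NF1	0	+
chr17	37844000	37886000	ERBB2	0	+
chr22	24129000	24176000	SMARCB1	0	+
chr22	29999000	30094000	NF2	0	+
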