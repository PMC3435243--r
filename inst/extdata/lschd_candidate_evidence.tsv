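gene	fusion_p	sage_fold	flag	transmission	location
ANG/RNASE4	0.000376	nd	+	inherited	Chr14q11.2
MAPK7	0.000122	8.15	-	de_novo	Chr17p11.2
NCOR1	0.000937	nd	+	de_novo	Chr17p11.2
ADORA2B	0.00379	nd	+	de_novo	Chr17p11.2
MFAP4	0.00288	11.64	+	de_novo	Chr17p11.2
COPS3	0.00379	nd	+	de_novo	Chr17p11.2
FLII	0.00187	nd	+	de_novo	Chr17p11.2
MSX1	0.0049	7.36	NA	de_novo	Chr4p16
SREBF1	0.00786	nd	+	de_novo	Chr17p11.2
SMC1A	0.00906	nd	+	inherited	ChrXp11.22
LIMS1	0.00496	nd	+	inherited	Chr2q12
CACNA1C	0.00734	nd	+	unknown	Chr12p13
CRMP1	0.0156	10.96	-	de_novo	Chr4p16
RASD1	0.0107	12.83	-	de_novo	Chr17p11.2
ERCC5	0.0139	5.65	-	inherited	Chr13q33
ULK2	0.0287	nd	+	de_novo	Chr17p11.2
PLA2G12A	0.0409	3.61	-	unknown	Chr10q22
NGEF	0.0454	nd	+	inherited	Chr2q37
GRPEL1	0.11	3.10	+	de_novo	Chr4p16
PRPSAP2	0.34	3.49	+	de_novo	Chr17p11.2
MTHFD2	0.84	6.14	+	de_novo	Chr2p13
EVC2	0.74	6.19	+	de_novo	Chr4p16
CTHRC1	0.17	27.85	+	de_novo	Chr8q22
ITGA10	0.00348	nd	+	de_novo	Chr1q21
HSD17B10	0.0281	nd	+	inherited	chrXp11.22
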