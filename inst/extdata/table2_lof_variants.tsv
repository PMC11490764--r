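class_printed	gene	locus	rsid	het_pct	mechanism	protein_pct	loh
1	SYNE2	14q23.2	rs2781377	94	stop_snv	58.11	Colon:0.15;Kidney:0.22;Ovarian:0.20;Melanoma:0.14
1	UBE2NL	Xq27.3	rs237520	48	stop_snv	57.79	Lung:0.26;Ovarian:0.30;Neuroblastoma:0.24;Neuroglial:0.20
1	CLDN5	22q11.21	rs885985	44	stop_snv	12.21	Lung:0.27
1	FUT2	19q13.33	rs601338	35	stop_snv	44.77	Lung:0.25;Ovarian:0.18
1	C17orf77	17q25.1	rs545652	26	stop_snv	85.19	Lung:0.17;Ovarian:0.24
1	ARMS2	10q26.13	rs2736911	22	stop_snv	35.51	Lung:0.22;Ovarian:0.18;Melanoma:0.23;Neuroblastoma:0.15
1	MROH2B	5p13.1	rs1023840	22	stop_snv	12.05	Lung:0.16;Ovarian:0.15
1	PRB4	12p13.2	rs12829245	18	stop_snv	21.91	Lung:0.20;Ovarian:0.17;Melanoma:0.15
1	ARMC3	10p12.2	rs190663005	17	stop_snv	75.61	Lung:0.24;Ovarian:0.23;Melanoma:0.20;Neuroglial:0.31
1	HLA-DQB1	6p21.32	rs1130385	17	stop_snv	40.46	Lung:0.17;Ovarian:0.15
1	AP3M1	10q22.2	rs190136804	15	stop_snv	61.72	Lung:0.22;Melanoma:0.20;Neuroglial:0.30
1	EIF3CL	16p11.2	rs201261076	15	stop_snv	63.79	Lung:0.20;Ovarian:0.18
1	PRAMEF2	1p36.21	rs75411676	15	stop_snv	44.51	Breast:0.19;Colon:0.18;Lung:0.26;Ovarian:0.19;Melanoma:0.18;Neuroblastoma:0.50
1	SPERT	13q14.13	rs79707842	14	stop_snv	60.68	Lung:0.29;Ovarian:0.20
1	OBSCN	1q42.13	rs3795786	11	stop_snv	42.64	Lung:0.20;Ovarian:0.20
1	ZNF860	3p23	rs4639011	11	stop_snv	22.63	Kidney:0.49;Lung:0.44;Ovarian:0.18;Melanoma:0.29;Neuroblastoma:0.15
2	CCDC182	17q22	rs12451748	49	splice_snv	NA	Lung:0.17;Ovarian:0.21
2	HTR3D	3q27.1	rs6443930	47	splice_snv	NA	Ovarian:0.18;Melanoma:0.28
2	TOR1AIP1	1q25.2	rs2245425	44	splice_snv	NA	Lung:0.16
2	ZNF419	19q13.43	rs2074071	43	splice_snv	NA	Lung:0.25;Ovarian:0.18
2	EMR1	19p13.3	rs330880	42	splice_snv	NA	Lung:0.22;Ovarian:0.15
2	GSDMB	17q12	rs11078928	42	splice_snv	NA	Lung:0.18;Ovarian:0.21
2	OAS1	12q24.13	rs10774671	41	splice_snv	NA	Melanoma:0.16
2	TMPRSS4	11q23.3	rs2276122	35	splice_snv	NA	Ovarian:0.18;Melanoma:0.19;Neuroblastoma:0.19
2	TBC1D31	8q24.13	rs10101626	32	splice_snv	NA	Lung:0.21;Ovarian:0.21
2	C14orf105	14q22.3	rs1152522	30	splice_snv	NA	Kidney:0.22;Lung:0.21;Ovarian:0.21
2	C14orf159	14q32.11	rs4900072	29	splice_snv	NA	Lung:0.22;Ovarian:0.20
2	NPHP4	1p36.31	rs1287637	28	splice_snv	NA	Breast:0.20;Colon:0.18;Lung:0.26;Ovarian:0.19;Melanoma:0.18;Neuroblastoma:0.50
2	TNK1	17p13.1	rs7220814	17	splice_snv	NA	Colon:0.31;Lung:0.35;Ovarian:0.24;Melanoma:0.15
2	CYP2D6	22q13.2	rs3892097	16	splice_snv	NA	Lung:0.28;Ovarian:0.25;Neuroblastoma:0.18;Neuroglial:0.22
2	MPP2	17q21.31	rs231518	15	splice_snv	NA	Lung:0.17;Ovarian:0.21
2	EFCAB13	17q21.32	rs76299620	11	splice_snv	NA	Lung:0.17;Ovarian:0.21
2	SLC22A14	3p22.2	rs753331	11	splice_snv	NA	Kidney:0.49;Lung:0.44;Ovarian:0.18;HeadNeck:0.19;Melanoma:0.29;Neuroblastoma:0.15
2	CES5A	16q12.2	rs72810507	10	splice_snv	NA	Lung:0.17;Ovarian:0.15;Melanoma:0.21
2	ENDOV	17q25.3	rs41298712	10	splice_snv	NA	Lung:0.17;Ovarian:0.21
3	ZNF880	19q13.41	rs34470614	43	frameshift_indel	18.37	Lung:0.25;Ovarian:0.18
3	C10orf113	10p12.31	rs72102767	35	frameshift_indel	40.51	Lung:0.22;Ovarian:0.15;Melanoma:0.20;Neuroblastoma:0.15;Neuroglial:0.30
3	EBLN2	3p13	NT73111480chr3	28	frameshift_indel	30.88	Kidney:0.48;Lung:0.40;Ovarian:0.18;HeadNeck:0.19;Melanoma:0.28
3	GLT6D1	19q34.3	rs34217442	27	frameshift_indel	51.81	Lung:0.31;Ovarian:0.18
3	CD200R1L	3q13.2	rs58161637	27	frameshift_indel	72.8	Kidney:0.16;Melanoma:0.28
3	C12orf60	12p12.3	rs139293175	26	frameshift_indel	75.1	Ovarian:0.15
3	RAI1	17p11.2	rs35068024	23	frameshift_indel	14.69	Colon:0.29;Lung:0.29;Ovarian:0.23
3	AKAP3	12p13.32	rs67512580	22	frameshift_indel	82.06	Lung:0.20;Ovarian:0.17;Melanoma:0.15
3	ZNF681	19p12	rs61397759	22	frameshift_indel	31.47	Lung:0.22;Ovarian:0.15
3	PRR25	16p13.3	rs138733834	21	frameshift_indel	58.71	Lung:0.21;Ovarian:0.16;Melanoma:0.21
3	ZNF812	19p13.2	rs112014279	18	frameshift_indel	53.96	Lung:0.24;Ovarian:0.19
3	SLFN12L	17q12	rs143471015	12	frameshift_indel	22.11	Lung:0.18;Ovarian:0.21
3	MUC22	6p21.33	rs112064513	11	frameshift_indel	35.93	Lung:0.17;Ovarian:0.15
4	NEK3	13q14.3	rs3837575	43	splice_indel	NA	Lung:0.29;Ovarian:0.20
4	ATG2B	14q32.2	rs34296665	42	splice_indel	NA	Lung:0.22;Ovarian:0.20
4	SPATA6L	9p24.1	rs34533529	38	splice_indel	NA	Lung:0.38;Ovarian:0.18;Melanoma:0.18;Neuroglial:0.19
4	NFKBIZ	3q12.3	rs3217713	31	splice_indel	NA	Kidney:0.16;Melanoma:0.28
4	MPRIP	17p11.2	rs3215213	29	splice_indel	NA	Colon:0.29;Lung:0.29;Ovarian:0.23
4	TMPRSS3	21q22.3	rs56283966	25	splice_indel	NA	Lung:0.26;Ovarian:0.24
4	A2M	12p13.31	rs3832852	23	splice_indel	NA	Lung:0.20;Ovarian:0.17;Melanoma:0.15
4	PDZRN3	3p13	rs200593963	21	splice_indel	NA	Kidney:0.48;Lung:0.40;Ovarian:0.18;HeadNeck:0.19;Melanoma:0.28
4	SLC3A1	2p21	rs61179824	17	splice_indel	NA	Ovarian:0.15
5	GSTT2	22q11.23	rs201176441	29	stop_snv	80.33	Lung:0.27
5	GSTT2	22q11.23	rs76498342	33	splice_snv	NA	Lung:0.27
5	GSTT2B	22q11.23	rs200376763	26	stop_snv	80.33	Lung:0.27
5	GSTT2B	22q11.23	rs181983734	25	splice_snv	NA	Lung:0.27
5	CYP4B1	1p33	rs3215983	25	frameshift_indel	57.53	Breast:0.19;Colon:0.18;Lung:0.26;Ovarian:0.19;Melanoma:0.18;Neuroblastoma:0.50
5	CYP4B1	1p33	rs3215983	25	splice_indel	NA	Breast:0.19;Colon:0.18;Lung:0.26;Ovarian:0.19;Melanoma:0.18;Neuroblastoma:0.50
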