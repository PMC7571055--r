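variant	name	display	locus	type	cys	predicted_mass	sim_mass	accession	notes
1Ax1	1Ax1	1	Glu-A1	x	4	87679	87679	X61009	
1Ax2*	1Ax2*	2*	Glu-A1	x	4	86335	86335	M22208	
1Bx6	1Bx6	6	Glu-B1	x	4	86523	86523	KX454509	
1Bx7g1	1Bx7	7	Glu-B1	x	4	82527	82527	X13927	group 1
1Bx7g2	1Bx7	7	Glu-B1	x	4	82527	83122	X13927	group 2; 18 bp coding insertion; simulation mass from the duplication-allele gene sequence shown identical in group 2 cultivars
1Bx7OE	1Bx7OE	7OE	Glu-B1	x	4	83122	83122	EU157184	overexpression; gene duplication detectable only by PCR
1Bx13	1Bx13	13	Glu-B1	x	4	83209	83209	EF540764	
1Bx14	1Bx14	14	Glu-B1	x	4	82343	82343	KF733216	
1Bx17	1Bx17	17	Glu-B1	x	4	77960	78606	AB263219	predicted mass deviates >300 Da from measurements; simulation mass uses measured mean
1Bx20	1Bx20	20	Glu-B1	x	2	83895	83895	AJ437000	2 cysteine residues
1By8	1By8	8	Glu-B1	y	7	75159	75159	AY245797	
1By8*	1By8*	8*	Glu-B1	y	7		75230		no gene sequence available; simulation mass uses measured mean
1By9	1By9	9	Glu-B1	y	7	73517	73517	X61026	
1By15	1By15	15	Glu-B1	y	7	74738	74738	KF733215	
1By16	1By16	16	Glu-B1	y	7	77283	77283	EF540765	
1By18	1By18	18	Glu-B1	y	7	75187	75187	KF430649	
1By20	1By20	20	Glu-B1	y	7	75148	75148	LN828972	
1Dx2	1Dx2	2	Glu-D1	x	4	87007	87007	X03346	
1Dx2.2	1Dx2.2	2.2	Glu-D1	x	4	100886	100389	AY159367	predicted mass printed inconsistently in the source; table-consistent value used; simulation mass uses measured mean (range-edge accuracy loss)
1Dx4	1Dx4	4	Glu-D1	x	4		85706		no gene sequence available; simulation mass uses measured mean
1Dx5	1Dx5	5	Glu-D1	x	5	88126	88126	X12928	5 cysteine residues
1Dy10	1Dy10	10	Glu-D1	y	7	67475	67475	X12929	
1Dy12	1Dy12	12	Glu-D1	y	7	68713	68713	X03041	
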