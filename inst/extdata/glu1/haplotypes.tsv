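locus	label	x	y
Glu-A1	1	1	
Glu-A1	2*	2*	
Glu-A1	N		
Glu-B1	6+8*	6	8*
Glu-B1	7+8	7	8
Glu-B1	7+8*	7	8*
Glu-B1	7+9	7	9
Glu-B1	7	7	
Glu-B1	7OE+8*	7OE	8*
Glu-B1	13+16	13	16
Glu-B1	14+15	14	15
Glu-B1	17+18	17	18
Glu-B1	20+20	20	20
Glu-D1	2+12	2	12
Glu-D1	2.2+12	2.2	12
Glu-D1	4+12	4	12
Glu-D1	5+10	5	10
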