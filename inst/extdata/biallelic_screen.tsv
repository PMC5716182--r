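gene	cell_line	clone_id	line_genotype	colonies_screened	colonies_positive
Brd8	JM8.N4	-	wt	24	23
Brd8	JM8.N4	E10	tm1a/+	22	22
Cbx1	JM8.N4	B01	tm1a/+	24	11
Ddx27	JM8.N4	-	wt	24	24
Ddx27	JM8.F6	E01	tm1a/+	6	0
Dot1l	JM8	D02	tm1a/+	24	13
Epc2	JM8	B12	tm1a/+	24	11
Ing3	JM8.N4	-	wt	24	19
Ing3	JM8.N4	E07	tm1a/+	16	13
Jarid2	JM8	A08	tm1a/+	24	15
Jarid2	JM8	E08	tm1a/+	24	15
Kdm4c	JM8.N4	-	wt	12	12
Kdm4c	JM8.F6	D03	tm1a/+	24	18
Mier1	JM8.N4	-	wt	24	16
Mier1	JM8.N4	A04	tm1a/+	24	16
Phf20	JM8.N4	-	wt	24	15
Phf20	JM8.N4	F07	tm1a/+	0	0
Setdb1	JM8.N4	-	wt	16	16
Setdb1	JM8.N4	D08	tm1a/+	40	0
Smyd5	JM8.N4	-	wt	16	10
Smyd5	JM8.N4	G01	tm1a/+	24	6
Supv3l1	JM8.N4	-	wt	24	12
Supv3l1	JM8.N4	B08	tm1a/+	24	17
Kmt5b	JM8	C01	tm1a/+	24	4
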