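# Nearest-neighbor Delta-G37 parameters (kcal/mol), formation convention.
# Stack keys: top dinucleotide 5'->3' "/" bottom dinucleotide 3'->5';
# either rotation may be written here, keys are canonicalized on load.
# Dangle keys: "X:AB" = unpaired X next to the terminal pair A(top)-B(bottom);
# dangle5 = X on the 5' side of A, dangle3 = X on the 3' side of A.
# P = pseudouridine.
type	key	dG37	citation
stack	AA/UU	-0.93	Xia1998
stack	AU/UA	-1.10	Xia1998
stack	UA/AU	-1.33	Xia1998
stack	CU/GA	-2.08	Xia1998
stack	CA/GU	-2.11	Xia1998
stack	GU/CA	-2.24	Xia1998
stack	GA/CU	-2.35	Xia1998
stack	CG/GC	-2.36	Xia1998
stack	GG/CC	-3.26	Xia1998
stack	GC/CG	-3.42	Xia1998
initiation	init	4.09	Xia1998
terminal	AU	0.45	Xia1998
terminal	GU	0.45	Xia1998
terminal	PA	0.31	Hudson2013
stack	UC/GG	-2.25	Chen2012
stack	GU/CG	-2.60	Chen2012
stack	CU/GG	-2.10	Turner2004
stack	CG/GU	-1.40	Turner2004
stack	GU/UG	1.30	Turner2004
stack	GG/UU	-0.50	Turner2004
stack	UG/GU	0.30	Turner2004
stack	AU/UG	-1.40	Turner2004
stack	AG/UU	-0.60	Turner2004
stack	UU/AG	-1.30	Turner2004
stack	UG/AU	-1.00	Turner2004
stack	PC/AG	-2.49	Hudson2013
stack	GP/CA	-3.29	Hudson2013
stack	AP/UA	-2.80	Hudson2013
stack	PU/AA	-2.74	Hudson2013
dangle5	A:CG	-0.5	Turner2004
dangle5	C:CG	-0.3	Turner2004
dangle5	G:CG	-0.2	Turner2004
dangle5	U:CG	-0.1	Turner2004
dangle5	A:GC	-0.2	Turner2004
dangle5	C:GC	-0.3	Turner2004
dangle5	G:GC	0.0	Turner2004
dangle5	U:GC	0.0	Turner2004
dangle5	A:GU	-0.3	Turner2004
dangle5	C:GU	-0.3	Turner2004
dangle5	G:GU	-0.4	Turner2004
dangle5	U:GU	-0.2	Turner2004
dangle5	A:UG	-0.3	Turner2004
dangle5	C:UG	-0.1	Turner2004
dangle5	G:UG	-0.2	Turner2004
dangle5	U:UG	-0.2	Turner2004
dangle5	A:AU	-0.3	Turner2004
dangle5	C:AU	-0.3	Turner2004
dangle5	G:AU	-0.4	Turner2004
dangle5	U:AU	-0.2	Turner2004
dangle5	A:UA	-0.3	Turner2004
dangle5	C:UA	-0.1	Turner2004
dangle5	G:UA	-0.2	Turner2004
dangle5	U:UA	-0.2	Turner2004
dangle3	A:GC	-1.1	Turner2004
dangle3	C:GC	-0.4	Turner2004
dangle3	G:GC	-1.3	Turner2004
dangle3	U:GC	-0.6	Turner2004
dangle3	A:CG	-1.7	Turner2004
dangle3	C:CG	-0.8	Turner2004
dangle3	G:CG	-1.7	Turner2004
dangle3	U:CG	-1.2	Turner2004
dangle3	A:UG	-0.7	Turner2004
dangle3	C:UG	-0.1	Turner2004
dangle3	G:UG	-0.7	Turner2004
dangle3	U:UG	-0.1	Turner2004
dangle3	A:GU	-0.8	Turner2004
dangle3	C:GU	-0.5	Turner2004
dangle3	G:GU	-0.8	Turner2004
dangle3	U:GU	-0.6	Turner2004
dangle3	A:UA	-0.7	Turner2004
dangle3	C:UA	-0.1	Turner2004
dangle3	G:UA	-0.7	Turner2004
dangle3	U:UA	-0.1	Turner2004
dangle3	A:AU	-0.8	Turner2004
dangle3	C:AU	-0.5	Turner2004
dangle3	G:AU	-0.8	Turner2004
dangle3	U:AU	-0.6	Turner2004
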