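# Published free-energy increments (ddG37, kcal/mol, formation sign) for
# adding a terminal U or P (pseudouridine) nucleotide or pair to a core
# duplex, with propagated sd; thermodynamic values from inverse-Tm plots.
# `extended_group`/`extended_variant` link each row to the extended duplex
# in psi_duplex_thermo.tsv. `predicted` is the published nearest-neighbor
# prediction where one was printed (citation tag alongside).
core	terminus	extended_group	extended_variant	ddG	ddG_sd	predicted	pred_citation
core1	5'U	g01	u	-0.78	0.28	-0.1	Serra1995-dangle
core1	5'P	g01	psi	-0.66	0.16	NA	NA
core1	5'U/3'A	g03	u	-1.88	0.37	-1.9	Xia1998
core1	5'P/3'A	g03	psi	-1.81	0.17	-2.18	Hudson2013
core1	5'U/3'G	g09	u	-1.78	0.39	-1.8	Chen2012
core1	5'P/3'G	g09	psi	-1.53	0.19	NA	NA
core1	5'U/3'U	g15	u	-0.86	0.23	-1.0	Turner-mismatch
core1	5'P/3'U	g15	psi	-1.41	0.17	NA	NA
core1	5'U/3'C	g18	u	-1.12	0.16	-0.9	Turner-mismatch
core1	5'P/3'C	g18	psi	-0.81	0.21	NA	NA
core2	3'U	g02	u	-0.97	0.31	-0.6	Freier1985-dangle
core2	3'P	g02	psi	-0.97	0.29	NA	NA
core2	3'U/5'A	g08	u	-2.18	0.37	-1.79	Xia1998
core2	3'P/5'A	g08	psi	-2.10	0.45	-2.98	Hudson2013
core2	3'U/5'G	g14	u	-2.44	0.28	-2.15	Chen2012
core2	3'P/5'G	g14	psi	-3.22	0.22	NA	NA
core2	3'U/5'U	g17	u	-1.05	0.16	-1.0	Turner-mismatch
core2	3'P/5'U	g17	psi	-1.83	0.23	NA	NA
core2	3'U/5'C	g20	u	-1.36	0.17	-1.2	Turner-mismatch
core2	3'P/5'C	g20	psi	-1.52	0.19	NA	NA
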