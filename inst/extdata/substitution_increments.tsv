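# Published free-energy increments (ddG37, kcal/mol, formation sign) for
# replacing the central U with P (pseudouridine), i.e. dG37(P duplex) -
# dG37(U analog), from inverse-Tm-plot values; root-sum-square sd.
# `group` links to psi_duplex_thermo.tsv (psi vs u variants of that group).
# `opposite` is the base opposite the substitution site; `predicted` is
# the published nearest-neighbor prediction where printed. two_state FALSE
# marks the pairing whose U analog melted in two transitions.
group	context	opposite	ddG	ddG_sd	predicted	two_state
g04	5'GPC/3'CAG	A	-0.71	0.55	-1.2	TRUE
g10	5'GPC/3'CGG	G	-1.40	0.34	NA	TRUE
g16	5'GPC/3'CUG	U	-0.77	0.14	NA	TRUE
g19	5'GPC/3'CCG	C	-0.27	0.05	NA	TRUE
g05	5'CPG/3'GAC	A	-2.43	0.49	-0.8	TRUE
g11	5'CPG/3'GGC	G	-0.43	0.14	NA	FALSE
g06	5'APU/3'UAA	A	-0.27	0.27	-3.5	TRUE
g12	5'APU/3'UGA	G	-0.82	0.10	NA	TRUE
g07	5'UPA/3'AAU	A	-0.55	0.19	-1.5	TRUE
g13	5'UPA/3'AGU	G	-0.84	0.07	NA	TRUE
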