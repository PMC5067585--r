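position	wt	mut	cohort_label	carriers	total	note
628	T	S	T-PLL	3	50	somatic, phosphotyrosine-binding pocket
642	N	H	NK/gd T-cell lymphoma	7	21	somatic, betaD5
642	N	H	NK/gd T-cell lymphoma	14	94	somatic, betaD5
642	N	H	T-PLL	11	50	somatic, betaD5
642	N	H	T-ALL	5	68	somatic, betaD5
642	N	H	pediatric T-ALL	19	301	somatic, betaD5
642	N	H	LGLL	4	211	somatic, betaD5
665	Y	F	T-PLL	3	50	somatic, hydrophobic acceptor interface
665	Y	F	NK/gd T-cell lymphoma	2	94	somatic, hydrophobic acceptor interface
665	Y	F	T-ALL	1	68	somatic, hydrophobic acceptor interface
665	Y	F	LGLL	2	211	somatic, hydrophobic acceptor interface
699	I	L	NK/gd T-cell lymphoma	1	94	somatic, pY+5; I704L in the STAT5B numbering; source text prints 2.0% which is inconsistent with 1/94
699	I	L	T-ALL	1	68	somatic, pY+5; I704L in the STAT5B numbering; source text prints 2.0% which is inconsistent with 1/68
701	Q	L	T-PLL	1	50	somatic, pY+7; Q706L in the STAT5B numbering
618	R	Q	engineered	NA	NA	non-functional control, invariant arginine of the pY pocket
633	F	A	engineered	NA	NA	hydrophobic acceptor interface probe
641	W	A	engineered	NA	NA	hydrophobic acceptor interface probe
665	Y	A	engineered	NA	NA	hydrophobic acceptor interface probe
706	F	A	engineered	NA	NA	intramolecular donor probe
706	F	G	engineered	NA	NA	intramolecular donor probe
710	S	F	engineered	NA	NA	gain-of-function, nTAD
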