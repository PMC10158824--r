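species	potential_md	annotation	gene_isoform_prediction	undetermined	true_md	pct_true_md
Yarrowia_lipolytica	186	114	9	0	63	33.9
Schizosaccharomyces_pombe	130	72	3	0	55	42.3
Arthrobotrys_oligospora	193	109	27	3	54	28.0
Tuber_melanosporum	236	116	58	6	56	23.7
Aspergillus_fumigatus	164	95	13	1	55	33.5
Neurospora_crassa	156	97	9	0	50	32.1
Eutypa_lata	294	124	90	33	47	16.0
Phaeosphaeria_nodorum	245	118	51	7	69	28.2
Cryptococcus_neoformans	181	97	4	2	78	43.1
Coprinopsis_cinerea	210	111	28	1	70	33.3
Wallemia_ichthyophaga	211	117	14	3	77	36.5
Ustilago_maydis	180	86	3	9	82	45.6
Microbotryum_violaceum	195	109	15	9	62	31.8
Puccinia_graminis	232	116	27	30	59	25.4
Mixia_osmundae	181	101	7	3	70	38.7
Allomyces_macrogynus	273	122	44	63	44	16.1
Spizellomyces_punctatus	144	72	9	12	51	35.4
Gonapodya_prolifera	207	97	33	6	71	34.3
Nosema_ceranae	178	63	17	56	42	23.6
Vavraia_culicis	191	72	3	28	88	46.1
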