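species	potential_ad	annotation	true_ad	pct_true_ad
Yarrowia_lipolytica	163	97	66	40.5
Schizosaccharomyces_pombe	174	94	80	46.0
Arthrobotrys_oligospora	207	113	94	45.4
Tuber_melanosporum	192	98	94	49.0
Aspergillus_fumigatus	199	100	99	49.7
Neurospora_crassa	195	102	93	47.7
Eutypa_lata	183	96	87	47.5
Phaeosphaeria_nodorum	237	98	139	58.6
Cryptococcus_neoformans	174	72	104	59.1
Coprinopsis_cinerea	212	87	125	59.0
Wallemia_ichthyophaga	277	77	200	72.2
Ustilago_maydis	221	83	138	62.4
Microbotryum_violaceum	211	80	131	62.1
Puccinia_graminis	159	73	86	54.1
Mixia_osmundae	316	86	228	72.6
Allomyces_macrogynus	173	67	106	61.3
Spizellomyces_punctatus	302	116	186	61.6
Gonapodya_prolifera	161	66	95	59.0
Nosema_ceranae	15	9	6	40.0
Vavraia_culicis	14	8	6	42.9
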