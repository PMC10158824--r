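species	potential_md	potential_ad	ratio_md_ad	total	pct_orthologs_with_events
Yarrowia_lipolytica	186	163	1.1	349	11.7
Schizosaccharomyces_pombe	130	174	0.7	304	12.4
Arthrobotrys_oligospora	193	207	0.9	400	14.8
Tuber_melanosporum	236	192	1.2	428	16.4
Aspergillus_fumigatus	164	199	0.8	363	13.4
Neurospora_crassa	156	195	0.8	351	13.1
Eutypa_lata	294	183	1.6	477	19.5
Phaeosphaeria_nodorum	245	237	1.0	482	18.6
Cryptococcus_neoformans	181	174	1.0	355	15.7
Coprinopsis_cinerea	210	212	1.0	422	18.4
Wallemia_ichthyophaga	211	277	0.8	488	23.9
Ustilago_maydis	180	221	0.8	401	17.7
Microbotryum_violaceum	195	211	0.9	406	17.8
Puccinia_graminis	232	159	1.5	391	18.5
Mixia_osmundae	181	316	0.6	497	22.5
Allomyces_macrogynus	273	173	1.6	446	21.0
Spizellomyces_punctatus	144	302	0.5	446	19.8
Gonapodya_prolifera	207	161	1.3	368	18.1
Nosema_ceranae	178	15	11.9	193	40.6
Vavraia_culicis	191	14	13.6	205	40.9
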