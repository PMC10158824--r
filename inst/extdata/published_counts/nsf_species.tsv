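species	contig_n50	busco_complete	n_coding_genes	n_orthologs	mean_pct_identity
Yarrowia_lipolytica	182835	95.7	6448	2889	36.1
Schizosaccharomyces_pombe	2923134	79.9	5145	2340	32.9
Arthrobotrys_oligospora	5390931	95.4	11479	2641	32.1
Tuber_melanosporum	63046	92.8	7496	2537	31.9
Aspergillus_fumigatus	556577	96.6	9623	2561	31.7
Neurospora_crassa	102005	97.9	9758	2615	31.5
Eutypa_lata	190808	97.0	11685	2350	31.0
Phaeosphaeria_nodorum	16751	93.2	12391	2502	30.3
Cryptococcus_neoformans	1423448	98.7	6632	2177	29.7
Coprinopsis_cinerea	3468139	98.8	13355	2161	29.6
Wallemia_ichthyophaga	436658	87.0	4865	1997	29.5
Ustilago_maydis	111545	99.1	6765	2199	29.0
Microbotryum_violaceum	1329596	94.4	7364	2202	28.8
Puccinia_graminis	53646	88.8	15800	1849	28.5
Mixia_osmundae	426173	88.4	6726	2111	28.1
Allomyces_macrogynus	35497	83.9	18774	402	28.2
Spizellomyces_punctatus	155888	90.9	8950	2100	29.8
Gonapodya_prolifera	63757	74.8	13827	1819	29.1
Nosema_ceranae	42592	93.5	2060	467	25.2
Vavraia_culicis	94471	95.5	2773	491	24.5
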