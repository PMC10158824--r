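species	potential_md	annotation	gene_isoform_prediction	undetermined	true_md	pct_true_md
Chimpanzee	237	107	63	57	10	4.2
Gorilla	480	180	81	180	39	8.1
Orangutan	400	103	246	11	40	10.0
Gibbon	763	337	116	293	17	2.4
Baboon	422	160	181	15	66	15.6
Vervet	746	208	253	164	121	16.2
Macaque	388	155	182	0	51	13.1
Marmoset	349	178	139	2	30	8.6
Bushbaby	677	285	107	248	37	5.5
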