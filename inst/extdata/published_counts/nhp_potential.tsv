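species	potential_md	potential_ad	ratio_md_ad	total	pct_orthologs_with_events
Chimpanzee	237	92	2.6	329	1.8
Gorilla	480	102	4.7	582	3.3
Orangutan	400	121	3.3	521	3.1
Gibbon	763	131	5.8	894	5.3
Baboon	422	154	2.7	576	3.3
Vervet	746	122	6.1	868	5.0
Macaque	388	199	1.9	587	3.6
Marmoset	349	139	2.5	488	2.9
Bushbaby	677	173	3.9	850	5.2
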