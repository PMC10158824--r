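species	potential_ad	annotation	isoform	true_ad	pct_true_ad
Chimpanzee	92	42	18	32	34.8
Gorilla	102	60	16	26	25.5
Orangutan	121	53	13	55	45.5
Gibbon	131	90	13	28	21.2
Baboon	154	79	15	60	39.0
Vervet	122	86	8	28	23.0
Macaque	199	77	20	102	51.3
Marmoset	139	90	12	37	26.6
Bushbaby	173	139	5	29	16.8
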