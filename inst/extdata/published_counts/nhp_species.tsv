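species	contig_n50	busco_complete	n_coding_genes	n_orthologs	mean_pct_identity
Chimpanzee	384816	96.0	23534	17944	98.5
Gorilla	52934	97.2	21794	17670	98.2
Orangutan	11074009	99.3	20211	16490	97.3
Gibbon	35148	99.7	20794	16797	96.5
Baboon	1465768	98.6	21882	17107	96.1
Vervet	90449	99.0	19165	17192	96.2
Macaque	46608966	98.8	21761	16255	95.9
Marmoset	13222669	99.9	22078	16714	94.0
Bushbaby	27100	97.4	19506	16071	89.4
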