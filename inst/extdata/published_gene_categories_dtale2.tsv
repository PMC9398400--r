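category	n_genes	n_expressed	n_up	n_down
intergenic	845	449	1	0
upstream	113	81	0	0
CDS	27	20	0	0
downstream	80	41	1	0
intron	29	21	0	0
3'UTR	6	6	0	0
5'UTR	10	8	0	0
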