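category	n_genes	n_expressed	n_up	n_down
intergenic	283	148	0	0
upstream	136	87	3	0
CDS	98	70	1	0
downstream	58	34	0	0
intron	25	17	1	0
3'UTR	18	17	0	0
5'UTR	11	7	0	0
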