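gene_id	site	bold_positions	location
OsKitaake11g227500	TGACGAGAGATAGCTTTCA	6,8,14,17	Downstream
OsKitaake08g030300	AGACGTGACATAGTTTCCA	1,6,8,9	Intergenic
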