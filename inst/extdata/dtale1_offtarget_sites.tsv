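gene_id	site	bold_positions	location
OsKitaake03g369100	ACCCCGCATAGCTGGACAA	1,15,19	CDS
OsKitaake02g392000	TCCCCACATATTTGATCAT	11,12,16	Upstream
OsKitaake07g118833	TCCCAGAATAGATGAACAT	5,7,12	Upstream
OsKitaake06g213800	TCCCAGCATGGCTGTCCAT	5,10,15,16	Upstream
OsKitaake04g082200	TGCCCGCGTTGCTGGACAT	2,8,10,15	Intron
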