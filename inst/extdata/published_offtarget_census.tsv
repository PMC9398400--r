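n_mismatch	dtale1	dtale2
1	0	0
2	2	0
3	36	23
4	475	1361
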