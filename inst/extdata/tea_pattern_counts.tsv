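category	clusters	count
additive	C1-C4	1723
higher-parent dominance	C5-C6	3804
lower-parent dominance	C7-C8	2338
up-overdominance	C9	1586
down-overdominance	C10	1299
total_genes	all	41781
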