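class	genotype	value	sd
GLV	HGY	432.93	79.04
GLV	JGY	584.62	91.38
GLV	TGY	400.67	66.53
GLV	HD	284.18	40.92
monoterpene	HGY	1500.79	396.8
monoterpene	JGY	1555.90	143.99
monoterpene	TGY	766.43	117.94
monoterpene	HD	916.7	73.39
sesquiterpene	HGY	42.58	6.77
sesquiterpene	JGY	24.98	4.19
sesquiterpene	TGY	22.28	2.58
sesquiterpene	HD	16.18	1.18
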