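compound	class	genotype	mean	sd
Hexanal	GLV	HGY	56.1	12.86
Hexanal	GLV	JGY	91.4	17.77
Hexanal	GLV	TGY	43.92	11.85
Hexanal	GLV	HD	42.33	5.75
(E)-2-Hexenal	GLV	HGY	72.5	21.88
(E)-2-Hexenal	GLV	JGY	225.95	40.01
(E)-2-Hexenal	GLV	TGY	127.13	11.51
(E)-2-Hexenal	GLV	HD	60.23	8.07
(E)-3-Hexen-1-ol	GLV	HGY	92.84	30.95
(E)-3-Hexen-1-ol	GLV	JGY	80.86	7.94
(E)-3-Hexen-1-ol	GLV	TGY	77.22	3.49
(E)-3-Hexen-1-ol	GLV	HD	84.44	22.07
(Z)-2-Hexen-1-ol	GLV	HGY	10.66	1
(Z)-2-Hexen-1-ol	GLV	JGY	13.78	1.61
(Z)-2-Hexen-1-ol	GLV	TGY	5.83	0.61
(Z)-2-Hexen-1-ol	GLV	HD	3.28	0.59
1-Hexanol	GLV	HGY	84.97	14.18
1-Hexanol	GLV	JGY	69.65	8.29
1-Hexanol	GLV	TGY	33.79	12.23
1-Hexanol	GLV	HD	27.11	9.48
(Z)-3-Hexen-1-ol acetate	GLV	HGY	116.31	32.14
(Z)-3-Hexen-1-ol acetate	GLV	JGY	102.98	22.15
(Z)-3-Hexen-1-ol acetate	GLV	TGY	115.78	19.19
(Z)-3-Hexen-1-ol acetate	GLV	HD	66.79	2.6
Linalool oxide 1	monoterpene	HGY	289.92	92.76
Linalool oxide 1	monoterpene	JGY	284.78	25.62
Linalool oxide 1	monoterpene	TGY	115.73	23.83
Linalool oxide 1	monoterpene	HD	190.75	4.42
Linalool oxide 2	monoterpene	HGY	509.3	98.74
Linalool oxide 2	monoterpene	JGY	287.01	20.36
Linalool oxide 2	monoterpene	TGY	241.48	69.98
Linalool oxide 2	monoterpene	HD	116.86	59.02
Linalool	monoterpene	HGY	387.86	66.16
Linalool	monoterpene	JGY	447.12	51.29
Linalool	monoterpene	TGY	222.01	73.24
Linalool	monoterpene	HD	310.64	42.1
beta-Cyclocitral	monoterpene	HGY	11.72	2.29
beta-Cyclocitral	monoterpene	JGY	4.15	0.79
beta-Cyclocitral	monoterpene	TGY	3.55	1.06
beta-Cyclocitral	monoterpene	HD	2.34	0.83
cis-Citral	monoterpene	HGY	8.83	3.18
cis-Citral	monoterpene	JGY	20.42	2.65
cis-Citral	monoterpene	TGY	8.31	0.75
cis-Citral	monoterpene	HD	2.97	0.23
(Z)-Geraniol	monoterpene	HGY	4.88	1.22
(Z)-Geraniol	monoterpene	JGY	6.75	1.07
(Z)-Geraniol	monoterpene	TGY	7.69	1.71
(Z)-Geraniol	monoterpene	HD	32.9	6.66
Geraniol	monoterpene	HGY	288.28	29.56
Geraniol	monoterpene	JGY	505.67	42.21
Geraniol	monoterpene	TGY	164.19	26
Geraniol	monoterpene	HD	257.69	58.04
Germacrene D	sesquiterpene	HGY	5.49	1.01
Germacrene D	sesquiterpene	JGY	1.27	0.08
Germacrene D	sesquiterpene	TGY	0.34	0.09
Germacrene D	sesquiterpene	HD	0.47	0.05
Germacrene B	sesquiterpene	HGY	6.14	1.76
Germacrene B	sesquiterpene	JGY	1.47	0.17
Germacrene B	sesquiterpene	TGY	1.39	0.33
Germacrene B	sesquiterpene	HD	1.02	0.15
alpha-Farnesene	sesquiterpene	HGY	0	0
alpha-Farnesene	sesquiterpene	JGY	7.5	0.64
alpha-Farnesene	sesquiterpene	TGY	0	0
alpha-Farnesene	sesquiterpene	HD	0	0
Cubenene	sesquiterpene	HGY	10.21	1.22
Cubenene	sesquiterpene	JGY	0	0
Cubenene	sesquiterpene	TGY	6.4	1.61
Cubenene	sesquiterpene	HD	0	0
Nerolidol 2	sesquiterpene	HGY	20.74	3.78
Nerolidol 2	sesquiterpene	JGY	14.74	3.81
Nerolidol 2	sesquiterpene	TGY	14.15	1.77
Nerolidol 2	sesquiterpene	HD	14.69	1.23
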