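category	lineage	family	level	prop_male	prop_female
Retroelements			subtotal	49.7	51.4
Retroelements	Ty3_gypsy		subtotal	35.7	37.5
Retroelements	Ty3_gypsy	Ogre	leaf	11.94	13.24
Retroelements	Ty3_gypsy	Tat	leaf	2.38	2.51
Retroelements	Ty3_gypsy	Athila	leaf	11.95	12.22
Retroelements	Ty3_gypsy	Tekay	leaf	6.90	6.99
Retroelements	Ty3_gypsy	CRM	leaf	0.26	0.26
Retroelements	Ty3_gypsy	other	leaf	0.34	0.35
Retroelements	Ty1_copia		subtotal	13.7	13.7
Retroelements	Ty1_copia	Angela	leaf	11.75	11.83
Retroelements	Ty1_copia	Maximus	leaf	1.65	1.64
Retroelements	Ty1_copia	other	leaf	0.28	0.27
Retroelements	TRIM	TRIM	leaf	0.04	0.04
Retroelements	LINE	LINE	leaf	0.23	0.23
DNA_transposons			subtotal	1.45	1.44
DNA_transposons	CACTA	CACTA	leaf	1.25	1.25
DNA_transposons	Mutator	Mutator	leaf	0.20	0.19
Satellites			subtotal	3.09	3.19
Satellites		STAR-C	leaf	1.92	1.93
Satellites		X43.1	leaf	0.99	1.11
Satellites		15Ssp	leaf	0.09	0.08
Satellites		TRAYC-like	leaf	0.09	0.08
rDNA		45S_rDNA	leaf	0.31	0.44
rDNA		5S_rDNA	leaf	0.03	0.04
unclassified		unclassified	leaf	6.89	6.72
TOTAL			total	61.4	63.3
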