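gene	direction	n_total	n_pos	n_neg	product_name
SERPINA6	up	287	182	105	Serpin A6
GLIPR1	up	257	153	104	Glioma pathogenesis-related protein 1
SERPINE1	up	255	152	103	Serpin E1
ADAMTS9	up	235	132	103	A disintegrin and metalloprotease with thrombospondin motifs 9
TIMP1	up	224	123	101	Tissue inhibitor of metalloprotease 1
IL15	up	219	112	97	Interleukin 15
CYTL1	down	283	106	177	Cytokine-like protein 1
NDP	down	281	104	171	Norrin
SPP1	down	269	89	180	Osteopontin
C1QTNF7	down	267	104	163	C1q and tumor necrosis factor-related protein 7
LYPD6	down	254	84	170	Ly6/PLAUR domain-containing 6
LUM	down	251	95	156	Lumican
CYR61	down	250	93	157	Cell communication network factor 1
ABI3BP	down	239	95	144	ABI family member 3 binding protein
CST6	down	233	74	159	Cystatin E/M
PLA2G7	down	215	76	139	Phospholipase A2 group VII
OMD	down	204	100	104	Osteomodulin
MFAP5	down	202	61	141	Microfibril associated protein 5
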