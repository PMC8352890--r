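gene	product_class	direction	log2fc_bifurcation	q_bifurcation	log2fc_straight	q_straight
CHI3L2	enzyme	up	11.88	0.0469	0.00	1.0000
SERPINA6	other	up	10.72	0.0084	5.06	0.4320
HBEGF	growth factor	up	4.80	0.0014	1.08	1.0000
TIMP1	cytokine	up	4.52	0.0000	3.74	0.0000
ADAMTS9	peptidase	up	4.08	0.0013	2.70	0.1782
SERPINE1	other	up	3.91	0.0000	2.49	0.0216
SEMA3F	other	up	3.39	0.0022	2.12	0.3327
BMP2	growth factor	up	3.35	0.0497	0.34	1.0000
IL15	cytokine	up	3.11	0.0142	1.79	0.6464
PLAT	peptidase	up	2.77	0.0261	1.35	0.8802
ADAMTS6	peptidase	up	2.63	0.0456	1.74	0.6622
GLIPR1	other	up	1.06	0.5043	2.42	0.0340
PTN	growth factor	down	-17.17	0.0000	-7.86	0.2483
PROS1	other	down	-14.76	0.0019	-1.58	1.0000
MFAP5	other	down	-12.86	0.0030	-9.54	0.1498
VIT	other	down	-12.80	0.0030	1.44	1.0000
CST6	other	down	-12.76	0.0107	-8.97	0.3702
C1QA	other	down	-12.48	0.0186	-0.78	1.0000
TTR	transporter	down	-12.18	0.0275	-7.27	0.7186
C2	peptidase	down	-11.60	0.0265	-2.14	1.0000
CXCL10	cytokine	down	-11.55	0.0027	3.42	0.7338
NID2	other	down	-10.86	0.0056	-0.75	1.0000
C1QTNF7	other	down	-10.64	0.0007	-8.63	0.0029
CXCL11	cytokine	down	-10.15	0.0322	-0.88	1.0000
BMP3	growth factor	down	-9.57	0.0045	-0.12	1.0000
HP	peptidase	down	-9.10	0.0080	-1.54	1.0000
C1QC	other	down	-8.76	0.0056	-1.71	1.0000
ITIH2	other	down	-8.61	0.0206	1.24	1.0000
IGF1	growth factor	down	-8.54	0.0339	0.80	1.0000
PLA2G7	enzyme	down	-8.30	0.0112	-3.68	0.7504
LYPD6	other	down	-7.78	0.0182	-9.65	0.0609
RSPO3	kinase	down	-6.86	0.0664	5.41	0.9693
ANGPTL4	other	down	-6.76	0.0253	-2.53	0.9693
NDP	growth factor	down	-6.71	0.0583	-10.76	0.0216
SPP1	cytokine	down	-5.39	0.0004	-4.13	0.0216
IGFBP2	other	down	-5.12	0.0286	-2.92	0.6982
OGN	growth factor	down	-4.91	0.0000	-2.19	0.3549
SERPINF1	other	down	-4.70	0.0322	1.87	0.9852
CYTL1	cytokine	down	-4.14	0.0008	-3.74	0.0073
LUM	other	down	-4.07	0.2310	-14.04	0.0007
OMD	other	down	-3.91	0.0000	-2.94	0.0073
ISG15	other	down	-3.56	0.0024	0.01	1.0000
LCAT	enzyme	down	-3.52	0.0417	-1.14	1.0000
ABI3BP	other	down	-3.21	0.0196	-3.57	0.0216
CYR61	other	down	-3.12	0.0126	-1.61	0.7504
SELENOP	other	down	-2.83	0.0040	-1.84	0.3549
COL14A1	other	down	-2.82	0.0117	-0.79	1.0000
IGFBP6	other	down	-2.81	0.0042	-0.52	1.0000
SAMD9L	other	down	-2.41	0.0483	0.92	1.0000
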