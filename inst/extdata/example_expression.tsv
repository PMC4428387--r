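gene	C1	C2	C3	T1	T2
EGFR	98	105	101	410	395
ERBB2	120	114	126	340	310
SOS1	80	84	76	150	118
PTEN	200	190	210	52	61
TP53	150	144	156	58	49
BAX	90	95	85	40	47
CASP3	110	104	116	52	75
BCL2	70	74	66	215	180
CCND1	130	124	136	128	131
CDK4	100	96	104	99	103
RB1	160	152	168	158	149
CDKN1A	85	90	80	88	84
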