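pathway_id	pathway_name	gene	arr
EGFR_SIG	EGFR signaling (synthetic demo)	EGFR	1.0
EGFR_SIG	EGFR signaling (synthetic demo)	ERBB2	1.0
EGFR_SIG	EGFR signaling (synthetic demo)	SOS1	0.5
EGFR_SIG	EGFR signaling (synthetic demo)	PTEN	-1.0
APOPTOSIS	Apoptosis (synthetic demo)	TP53	1.0
APOPTOSIS	Apoptosis (synthetic demo)	BAX	1.0
APOPTOSIS	Apoptosis (synthetic demo)	CASP3	1.0
APOPTOSIS	Apoptosis (synthetic demo)	BCL2	-1.0
CELL_CYCLE	Cell cycle (synthetic demo)	CCND1	1.0
CELL_CYCLE	Cell cycle (synthetic demo)	CDK4	1.0
CELL_CYCLE	Cell cycle (synthetic demo)	RB1	-1.0
CELL_CYCLE	Cell cycle (synthetic demo)	CDKN1A	-0.5
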