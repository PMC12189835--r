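group_a	chain_a	region_a	resname_a	aa_a	imgt_a	resno_a	icode_a	kind	distance	partners	group_b	chain_b	region_b	resname_b	aa_b	imgt_b	resno_b	icode_b
V-GAMMA	G	CDR1	ASN	N	37	31		HBOND_SS	3.1	synthetic	V-DELTA	D	CDR3	ASP	D	111.9	107	
V-GAMMA	G	CDR1	TYR	Y	38	32		HBOND_SS	3.1	synthetic	V-DELTA	D	CDR3	ARG	R	111.7	105	
V-GAMMA	G	FR2	HIS	H	40	34		IONIC	4.5	synthetic	V-DELTA	D	CDR3	ASP	D	111.9	107	
V-GAMMA	G	FR2	HIS	H	40	34		HBOND_SS	3.1	synthetic	V-DELTA	D	CDR3	ARG	R	112	123	
V-GAMMA	G	FR2	TYR	Y	42	36		CATION_PI	4.6	synthetic	V-DELTA	D	CDR3	ARG	R	112	123	
V-GAMMA	G	FR2	TYR	Y	42	36		HBOND_SS	3.1	synthetic	V-DELTA	D	CDR3	ARG	R	112	123	
V-GAMMA	G	FR2	PHE	F	44	38		AROMATIC_AROMATIC	5.8	synthetic	V-DELTA	D	FR3	PHE	F	103	91	
V-GAMMA	G	FR2	ARG	R	52	46		CATION_PI	4.6	synthetic	V-DELTA	D	CDR3	TRP	W	111.10	108	
V-GAMMA	G	FR2	TYR	Y	55	49		CATION_PI	4.6	synthetic	V-DELTA	D	CDR3	ARG	R	111.7	105	
V-GAMMA	G	FR2	TYR	Y	55	49		HBOND_SS	3.1	synthetic	V-DELTA	D	CDR3	ARG	R	111.7	105	
V-GAMMA	G	CDR3	TYR	Y	111.1	104		AROMATIC_AROMATIC	5.8	synthetic	V-DELTA	D	FR2	PHE	F	52	47	
V-GAMMA	G	CDR3	SER	S	112	106		HBOND_SS	3.1	synthetic	V-DELTA	D	CDR3	TRP	W	112.6	117	
V-GAMMA	G	CDR3	TRP	W	114	108		CATION_PI	4.6	synthetic	V-DELTA	D	CDR3	ARG	R	111.4	102	
V-GAMMA	G	CDR3	ARG	R	115	109		CATION_PI	4.6	synthetic	V-DELTA	D	FR2	PHE	F	52	47	
V-GAMMA	G	CDR3	ARG	R	115	109		HBOND_SS	3.1	synthetic	V-DELTA	D	CDR3	ASP	D	107	94	
V-GAMMA	G	CDR3	LYS	K	116	110		IONIC	4.5	synthetic	V-DELTA	D	CDR3	ASP	D	107	94	
V-GAMMA	G	CDR3	LYS	K	116	110		HBOND_SS	3.1	synthetic	V-DELTA	D	CDR3	ASP	D	107	94	
V-GAMMA	G	CDR3	LYS	K	116	110		CATION_PI	4.6	synthetic	V-DELTA	D	CDR3	TYR	Y	111.2	100	
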