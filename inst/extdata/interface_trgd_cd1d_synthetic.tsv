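group_a	chain_a	region_a	resname_a	aa_a	imgt_a	resno_a	icode_a	kind	distance	partners	group_b	chain_b	region_b	resname_b	aa_b	imgt_b	resno_b	icode_b
V-DELTA	D	CDR1	TRP	W	29	29		AROMATIC_AROMATIC	5.8	synthetic	CD1D	C	G-ALPHA1-LIKE	PHE	F	55	76	
V-DELTA	D	CDR3	ARG	R	111.7	105		IONIC	4.5	synthetic	CD1D	C	G-ALPHA1-LIKE	GLU	E	61	82	
V-DELTA	D	CDR3	ARG	R	111.7	105		HBOND_SS	3.1	synthetic	CD1D	C	G-ALPHA1-LIKE	ASN	N	62	83	
V-DELTA	D	CDR3	ASP	D	111.9	107		IONIC	4.5	synthetic	CD1D	C	G-ALPHA1-LIKE	HIS	H	65	86	
V-GAMMA	G	CDR1	TYR	Y	38	32		HBOND_SS	3.1	synthetic	CD1D	C	G-ALPHA1-LIKE	HIS	H	65	86	
V-GAMMA	G	CDR2	ASP	D	57	51		IONIC	4.5	synthetic	CD1D	C	G-ALPHA1-LIKE	HIS	H	65	86	
V-GAMMA	G	CDR2	LYS	K	64	56		IONIC	4.5	synthetic	CD1D	C	G-ALPHA1-LIKE	ASP	D	43	64	
V-DELTA	D	CDR1	SER	S	30	30		HBOND_SS	3.1	synthetic	CD1D	C	G-ALPHA2-LIKE	SER	S	72A	182	
V-DELTA	D	CDR3	ARG	R	109	96		CATION_PI	4.6	synthetic	CD1D	C	G-ALPHA2-LIKE	TRP	W	69	178	
V-DELTA	D	CDR3	TRP	W	111.5	103		AROMATIC_AROMATIC	5.8	synthetic	CD1D	C	G-ALPHA2-LIKE	TRP	W	69	178	
V-DELTA	D	FR2	ARG	R	55	50		IONIC	4.5	synthetic	CD1D	C	G-ALPHA2-LIKE	GLU	E	65	174	
V-DELTA	D	CDR3	ARG	R	111.4	102		IONIC	4.5	synthetic	CD1D	C	G-ALPHA2-LIKE	GLU	E	65	174	
V-DELTA	D	CDR3	ARG	R	111.4	102		HBOND_SS	3.1	synthetic	CD1D	C	G-ALPHA2-LIKE	GLU	E	65	174	
V-GAMMA	G	CDR3	TRP	W	114	108		HBOND_SS	3.1	synthetic	CD1D	C	G-ALPHA2-LIKE	GLU	E	65	174	
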