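group	species	organism	accession	protein	nols_start	nols_end	prediction
Mammals	H. sapiens	Homo sapiens	NP_001012333	Midkine	129	143	120-143
Mammals	H. sapiens	Homo sapiens	NP_055701	NSA2	10	41	none
Mammals	H. sapiens	Homo sapiens	NP_055701	NSA2	131	154	133-155
Mammals	H. sapiens	Homo sapiens	NP_872604	RASSF5	51	100	78-98
Mammals	H. sapiens	Homo sapiens	NP_037541	follistatin	93	116	98-121
Mammals	H. sapiens	Homo sapiens	CAA41051	histone H2B	28	35	15-42
Mammals	M. musculus	Mus musculus	NP_001012495	Cxcl12	98	118	92-119
Mammals	M. musculus	Mus musculus	NP_081208	NoBP	220	262	230-255;276-306
Mammals	M. musculus	Mus musculus	NP_082355	aminopeptidase O	688	725	682-712
Amoeba	D. discoideum	Dictyostelium discoideum	XP_002649205	eIF6	31	64	27-49
Amoeba	D. discoideum	Dictyostelium discoideum	XP_002649205	eIF6	246	252	295-320
Molluscs	A. kurodai	Aplysia kurodai	B0FRH7	ApLLP	1	19	1-21
Molluscs	A. kurodai	Aplysia kurodai	B0FRH7	ApLLP	90	120	96-120
Trypanosomes	T. brucei	Trypanosoma brucei	CAD21884	ESAG8	48	79	none
Trypanosomes	T. cruzi	Trypanosoma cruzi	XP_817097	Met-III	1	19	none
Trypanosomes	T. cruzi	Trypanosoma cruzi	XP_817097	Met-III	146	191	none
Plants	S. lycopersicum	Solanum lycopersicum	Q944N1	LHP1	141	171	141-165;276-296
Plants	A. thaliana	Arabidopsis thaliana	NP_001078269	HMGB1	1	47	22-60
Viruses (mammalian host)		Bovine herpesvirus 1	CAA90914	BICP27	86	97	75-108
Viruses (mammalian host)		Human Adenovirus C	YP_001551773	E4orf4	66	75	61-82
Viruses (mammalian host)		SARS coronavirus	P59633	Non-structural protein 3b	134	154	none
Viruses (mammalian host)		HTLV-1	BAH85789	Tof	71	98	none
Viruses (mammalian host)		Human herpes simplex virus	P08353	Gamma-1 34.5 protein	1	16	1-22
Viruses (mammalian host)		Human adenovirus 2	P68950	protein VII	93	112	90-117
Viruses (mammalian host)		African Swine Fever Virus	AAA87288	I14L	1	14	1-26
Viruses (mammalian host)		PRRSV (porcine)	AAD00244	N protein	41	48	1-21;32-59
Viruses (plant host)		Tomato Leaf Curl Java Virus	BAD90868	Capsid protein	1	30	none
Viruses (plant host)		Potato leafroll virus	P11624	Capsid protein	17	31	10-64
Viruses (avian host)		Marek's disease virus type 1	AAS01627	MEQ protein	62	78	22-47;52-81
Viruses (avian host)		Avian Infectious Bronchitis Virus	CAC39307	N protein	71	78	347-377
Viruses (fish host)		Betanodavirus GGNNV	NP_689432	Protein alpha	23	31	10-40
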