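PROTEOGLYCANS	proteoglycan signature	ACAN	VCAN	HSPG2	BGN	DCN	ASPN	FMOD	LUM	PRELP	OGN	HAPLN1
COLLAGENS	fibrillar and network collagens	COL1A1	COL1A2	COL2A1	COL3A1	COL4A1	COL4A2	COL5A1	COL5A2	COL6A1	COL6A2	COL6A3	COL15A1	COL18A1
BASEMENT_MEMBRANE	basement-membrane zone components	COL4A1	COL4A2	LAMA4	LAMA5	LAMB2	LAMC1	NID1	NID2	HSPG2	COL15A1	COL18A1
CORE_MATRISOME	all core-matrisome fixture genes	COL1A1	COL1A2	COL3A1	COL4A1	COL4A2	COL5A1	COL6A1	FN1	LAMA4	LAMB2	LAMC1	NID1	TNC	POSTN	THBS1	BGN	DCN	LUM	HSPG2	VCAN
GLYCOPROTEINS	ECM glycoproteins	FN1	LAMA4	LAMA5	LAMB2	LAMC1	NID1	NID2	MATN2	TINAGL1	VWA1	TNC	POSTN	THBS1	THBS2
ELASTIC_FIBERS	elastic-fiber assembly	FBN1	FBLN2	MFAP2	MFAP5	EMILIN1	LOX
ECM_REGULATORS	proteases and cross-linkers	CTSA	CTSB	CTSS	CTSZ	MMP2	MMP14	PLOD1	PLOD2	P4HA1	LOX	PLAUR	TIMP1	TIMP3
COAGULATION_COMPLEMENT	coagulation and complement cascade	C1QA	C1QB	C3	CFB	CFH	F2	FGA	FGB	FGG	PLG	SERPINA1	SERPINC1	SERPING1
SECRETED_FACTORS	secreted regulators	S100A4	S100A8	S100A9	S100A10	S100A11	CXCL12	TGFB1
ADHESION_CORE	integrin adhesion complex	ITGA5	ITGAV	ITGB1	TLN1	VCL	PXN	ZYX	FLNA	ACTN1	ILK	FERMT2	PTK2
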