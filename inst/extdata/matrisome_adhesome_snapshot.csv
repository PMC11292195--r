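gene,division,category
COL1A1,core_matrisome,collagens
COL1A2,core_matrisome,collagens
COL2A1,core_matrisome,collagens
COL3A1,core_matrisome,collagens
COL4A1,core_matrisome,collagens
COL4A2,core_matrisome,collagens
COL5A1,core_matrisome,collagens
COL5A2,core_matrisome,collagens
COL5A3,core_matrisome,collagens
COL6A1,core_matrisome,collagens
COL6A2,core_matrisome,collagens
COL6A3,core_matrisome,collagens
COL15A1,core_matrisome,collagens
COL18A1,core_matrisome,collagens
FN1,core_matrisome,glycoproteins
LAMA4,core_matrisome,glycoproteins
LAMA5,core_matrisome,glycoproteins
LAMB2,core_matrisome,glycoproteins
LAMC1,core_matrisome,glycoproteins
NID1,core_matrisome,glycoproteins
NID2,core_matrisome,glycoproteins
MATN2,core_matrisome,glycoproteins
TINAGL1,core_matrisome,glycoproteins
VWA1,core_matrisome,glycoproteins
FBN1,core_matrisome,glycoproteins
FBLN2,core_matrisome,glycoproteins
MFAP2,core_matrisome,glycoproteins
MFAP5,core_matrisome,glycoproteins
TNC,core_matrisome,glycoproteins
POSTN,core_matrisome,glycoproteins
THBS1,core_matrisome,glycoproteins
THBS2,core_matrisome,glycoproteins
EMILIN1,core_matrisome,glycoproteins
ACAN,core_matrisome,proteoglycans
VCAN,core_matrisome,proteoglycans
HSPG2,core_matrisome,proteoglycans
BGN,core_matrisome,proteoglycans
DCN,core_matrisome,proteoglycans
ASPN,core_matrisome,proteoglycans
FMOD,core_matrisome,proteoglycans
LUM,core_matrisome,proteoglycans
PRELP,core_matrisome,proteoglycans
OGN,core_matrisome,proteoglycans
HAPLN1,core_matrisome,proteoglycans
CTSA,matrisome_associated,ECM_regulators
CTSB,matrisome_associated,ECM_regulators
CTSS,matrisome_associated,ECM_regulators
CTSZ,matrisome_associated,ECM_regulators
MMP2,matrisome_associated,ECM_regulators
MMP14,matrisome_associated,ECM_regulators
PLOD1,matrisome_associated,ECM_regulators
PLOD2,matrisome_associated,ECM_regulators
P4HA1,matrisome_associated,ECM_regulators
LOX,matrisome_associated,ECM_regulators
PLAUR,matrisome_associated,ECM_regulators
SERPINA1,matrisome_associated,ECM_regulators
SERPINC1,matrisome_associated,ECM_regulators
SERPING1,matrisome_associated,ECM_regulators
ITIH1,matrisome_associated,ECM_regulators
ITIH2,matrisome_associated,ECM_regulators
TIMP1,matrisome_associated,ECM_regulators
TIMP3,matrisome_associated,ECM_regulators
S100A4,matrisome_associated,secreted_factors
S100A8,matrisome_associated,secreted_factors
S100A9,matrisome_associated,secreted_factors
S100A10,matrisome_associated,secreted_factors
S100A11,matrisome_associated,secreted_factors
CXCL12,matrisome_associated,secreted_factors
TGFB1,matrisome_associated,secreted_factors
C1QA,matrisome_associated,ECM_affiliated
C1QB,matrisome_associated,ECM_affiliated
C3,matrisome_associated,ECM_affiliated
CFB,matrisome_associated,ECM_affiliated
CFH,matrisome_associated,ECM_affiliated
F2,matrisome_associated,ECM_affiliated
FGA,matrisome_associated,ECM_affiliated
FGB,matrisome_associated,ECM_affiliated
FGG,matrisome_associated,ECM_affiliated
PLG,matrisome_associated,ECM_affiliated
ANXA1,matrisome_associated,ECM_affiliated
ANXA2,matrisome_associated,ECM_affiliated
GPC1,matrisome_associated,ECM_affiliated
SDC1,matrisome_associated,ECM_affiliated
ITGA5,adhesome,adhesion_receptor
ITGAV,adhesome,adhesion_receptor
ITGB1,adhesome,adhesion_receptor
ITGB3,adhesome,adhesion_receptor
ITGB5,adhesome,adhesion_receptor
SDC4,adhesome,adhesion_receptor
TLN1,adhesome,adaptor
TLN2,adhesome,adaptor
VCL,adhesome,adaptor
PXN,adhesome,adaptor
ZYX,adhesome,adaptor
TNS1,adhesome,adaptor
FLNA,adhesome,adaptor
FLNB,adhesome,adaptor
ACTN1,adhesome,adaptor
ACTN4,adhesome,adaptor
PARVA,adhesome,adaptor
ILK,adhesome,adaptor
LIMS1,adhesome,adaptor
FERMT2,adhesome,adaptor
CAV1,adhesome,adaptor
LCP1,adhesome,actin_regulator
CORO1A,adhesome,actin_regulator
CFL1,adhesome,actin_regulator
ARPC2,adhesome,actin_regulator
WASL,adhesome,actin_regulator
PTK2,adhesome,kinase
SRC,adhesome,kinase
ROCK1,adhesome,kinase
PAK1,adhesome,kinase
PTPN12,adhesome,phosphatase
FN1,adhesome,adhesion_ligand
THBS1,adhesome,adhesion_ligand
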