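# Small hand-checkable fixture molecules: SMILES <tab> identifier
CC	ethane
CCC	propane
CCCC	butane
CC(C)C	isobutane
CCCCC	pentane
CCCCCC	hexane
C1CC1	cyclopropane
C1CCC1	cyclobutane
C1CCCC1	cyclopentane
C1CCCCC1	cyclohexane
CO	methanol
CCO	ethanol
CC(C)O	isopropanol
OCC(O)CO	glycerol
CC(=O)O	acetic_acid
CC(C)=O	acetone
CCOC(C)=O	ethyl_acetate
CCOCC	diethyl_ether
NC=O	formamide
CC(N)=O	acetamide
CN	methylamine
CCN	ethylamine
Nc1ccccc1	aniline
c1ccccc1	benzene
Cc1ccccc1	toluene
Oc1ccccc1	phenol
C=Cc1ccccc1	styrene
O=Cc1ccccc1	benzaldehyde
OC(=O)c1ccccc1	benzoic_acid
c1ccc2ccccc2c1	naphthalene
c1ccncc1	pyridine
c1cncnc1	pyrimidine
c1cc[nH]c1	pyrrole
c1ccoc1	furan
c1ccsc1	thiophene
c1c[nH]cn1	imidazole
c1ccc2[nH]ccc2c1	indole
c1ccc2ncccc2c1	quinoline
C1CCNCC1	piperidine
C1COCCN1	morpholine
C1CCOC1	tetrahydrofuran
Clc1ccccc1	chlorobenzene
Fc1ccccc1	fluorobenzene
O=[N+]([O-])c1ccccc1	nitrobenzene
CC(=O)Oc1ccccc1C(=O)O	aspirin
Cn1cnc2c1c(=O)n(C)c(=O)n2C	caffeine
CC(C)Cc1ccc(cc1)C(C)C(=O)O	ibuprofen
CC(=O)Nc1ccc(O)cc1	paracetamol
CN1CCCC1c1cccnc1	nicotine
NC(=O)c1ccccc1	benzamide
CC#N	acetonitrile
C=CC=C	butadiene
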