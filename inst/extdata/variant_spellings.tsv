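# Two distinct SMILES spellings of the same molecule per row
smiles_a	smiles_b	id
CCO	OCC	ethanol
c1ccccc1	C1=CC=CC=C1	benzene
CC(C)C	C(C)(C)C	isobutane
c1ccncc1	n1ccccc1	pyridine
CC(=O)O	OC(C)=O	acetic_acid
c1ccc2ccccc2c1	C1=CC2=CC=CC=C2C=C1	naphthalene
CCN	NCC	ethylamine
CC(=O)Nc1ccc(O)cc1	Oc1ccc(NC(C)=O)cc1	paracetamol
CC(=O)Oc1ccccc1C(=O)O	OC(=O)c1ccccc1OC(C)=O	aspirin
C1CCCCC1	C2CCCCC2	cyclohexane
c1ccoc1	o1cccc1	furan
c1ccsc1	s1cccc1	thiophene
c1cc[nH]c1	[nH]1cccc1	pyrrole
CCCCC	C(CC)CC	pentane
CC(C)O	OC(C)C	isopropanol
CCOC(C)=O	CC(=O)OCC	ethyl_acetate
Cc1ccccc1	c1ccccc1C	toluene
Oc1ccccc1	c1ccc(O)cc1	phenol
Clc1ccccc1	c1ccc(Cl)cc1	chlorobenzene
C1CCOC1	O1CCCC1	tetrahydrofuran
CC#N	N#CC	acetonitrile
C=CC=C	C(=C)C=C	butadiene
O=C(C)Nc1ccccc1	CC(=O)Nc1ccccc1	acetanilide
CC(C)Cc1ccc(cc1)C(C)C(=O)O	OC(=O)C(C)c1ccc(CC(C)C)cc1	ibuprofen
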