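# Default alcohol building blocks (synthetic default set): SMILES<TAB>id
# 9 monofunctional
CO	MeOH
CCO	EtOH
CC(C)O	iPrOH
CCCCO	1-BuOH
CCCCCCO	1-HexOH
CCCCC(CC)CO	2-EtHexOH
CC(O)C(=O)OCCC(C)C	iPentyl-lactate
COCCO	2-MeO-EtOH
COCCOCCO	MeO-DEG
# 7 difunctional
OCCO	EG
OCCCCO	1,4-BDO
OCCCCCCO	1,6-HDO
OCCOCCO	DEG
CC(O)COCC(C)O	DPG
OCC(C)(C)CO	NPG
OCCOC(=O)CCCCC(=O)OCCO	BHEA
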