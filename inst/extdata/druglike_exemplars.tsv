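name	schembl_id	expected_class	smiles
sorbose	SCHEMBL762	RO5	OCC(=O)C(O)C(O)C(O)CO
mannose	SCHEMBL1812	RO5	OC[C@H]1OC(O)[C@@H](O)[C@@H](O)[C@H]1O
histidine	SCHEMBL3259	RO5	NC(Cc1c[nH]cn1)C(=O)O
arginine	SCHEMBL1790	RO5	NC(CCCNC(=N)N)C(=O)O
paclitaxel	SCHEMBL3976	BRO5	CC1=C2C(C(=O)C3(C(CC4C(C3C(C(C2(C)C)(CC1OC(=O)C(C(C5=CC=CC=C5)NC(=O)C6=CC=CC=C6)O)O)OC(=O)C7=CC=CC=C7)(CO4)OC(=O)C)O)C)OC(=O)C
doxorubicin	SCHEMBL3243	BRO5	CC1C(C(CC(O1)OC2CC(CC3=C2C(=C4C(=C3O)C(=O)C5=C(C4=O)C(=CC=C5)OC)O)(C(=O)CO)O)N)O
streptomycin	SCHEMBL3276	BRO5	CC1C(C(C(O1)OC2C(C(C(C(C2O)O)N=C(N)N)O)N=C(N)N)OC3C(C(C(C(O3)CO)O)O)NC)(C=O)O
bleomycin	SCHEMBL1599	BRO5	CC1=C(N=C(N=C1N)C(CC(=O)N)NCC(C(=O)N)N)C(=O)NC(C(C2=CN=CN2)OC3C(C(C(C(O3)CO)O)OC4C(C(C(C(O4)CO)O)O)OC(=O)N)O)C(=O)NC(C)C(C(C)C(=O)NC(C(C)O)C(=O)NCCC5=NC(=CS5)C6=NC(=CS6)C(=O)NCCC[S+](C)C)O
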