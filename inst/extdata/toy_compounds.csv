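name,smiles
methane,C
ethane,CC
propane,CCC
butane,CCCC
isobutane,CC(C)C
neopentane,CC(C)(C)C
benzene,c1ccccc1
cyclohexane,C1CCCCC1
ethanol,CCO
acetic_acid,CC(=O)O
toluene,Cc1ccccc1
pyridine,c1ccncc1
chlorobenzene,Clc1ccccc1
formamide,NC=O
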