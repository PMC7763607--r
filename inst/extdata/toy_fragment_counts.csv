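name,max_atoms,key,count
propane,3,L1|A|C,3
propane,3,L1|P|C-C,2
propane,3,L1|P|C-C-C,1
isobutane,4,L1|A|C,4
isobutane,4,L1|P|C-C,3
isobutane,4,L1|P|C-C-C,3
isobutane,4,L1|B|C(-C)(-C)(-C),1
neopentane,5,L1|A|C,5
neopentane,5,L1|P|C-C,4
neopentane,5,L1|P|C-C-C,6
neopentane,5,L1|B|C(-C)(-C)(-C),4
neopentane,5,L1|B|C(-C)(-C)(-C)(-C),1
benzene,6,L1|A|C,6
benzene,6,L1|P|C:C,6
benzene,6,L1|P|C:C:C,6
benzene,6,L1|P|C:C:C:C,6
benzene,6,L1|P|C:C:C:C:C,6
benzene,6,L1|R|C:C:C:C:C:C:,1
cyclohexane,6,L1|A|C,6
cyclohexane,6,L1|P|C-C,6
cyclohexane,6,L1|P|C-C-C,6
cyclohexane,6,L1|P|C-C-C-C,6
cyclohexane,6,L1|P|C-C-C-C-C,6
cyclohexane,6,L1|R|C-C-C-C-C-C-,1
ethanol,3,L1|A|C,2
ethanol,3,L1|A|O,1
ethanol,3,L1|P|C-C,1
ethanol,3,L1|P|C-O,1
ethanol,3,L1|P|C-C-O,1
acetic_acid,4,L1|A|C,2
acetic_acid,4,L1|A|O,2
acetic_acid,4,L1|P|C-C,1
acetic_acid,4,L1|P|C-O,1
acetic_acid,4,L1|P|C=O,1
acetic_acid,4,L1|P|C-C-O,1
acetic_acid,4,L1|P|C-C=O,1
acetic_acid,4,L1|P|O-C=O,1
acetic_acid,4,L1|B|C(-C)(-O)(=O),1
toluene,3,L1|A|C,7
toluene,3,L1|P|C-C,1
toluene,3,L1|P|C:C,6
toluene,3,L1|P|C-C:C,2
toluene,3,L1|P|C:C:C,6
formamide,3,L1|A|C,1
formamide,3,L1|A|N,1
formamide,3,L1|A|O,1
formamide,3,L1|P|C-N,1
formamide,3,L1|P|C=O,1
formamide,3,L1|P|N-C=O,1
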