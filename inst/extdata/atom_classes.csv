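residue,atom,class
*,C,3
*,O,6
*,N,4
*,OXT,7
PHE,CG,2
PHE,CD1,2
PHE,CD2,2
PHE,CE1,2
PHE,CE2,2
PHE,CZ,2
TYR,CG,2
TYR,CD1,2
TYR,CD2,2
TYR,CE1,2
TYR,CE2,2
TYR,CZ,2
TYR,OH,6
TRP,CG,2
TRP,CD1,2
TRP,CD2,2
TRP,NE1,5
TRP,CE2,2
TRP,CE3,2
TRP,CZ2,2
TRP,CZ3,2
TRP,CH2,2
HIS,CG,2
HIS,ND1,5
HIS,CD2,2
HIS,CE1,2
HIS,NE2,5
ASP,CG,3
ASP,OD1,7
ASP,OD2,7
GLU,CD,3
GLU,OE1,7
GLU,OE2,7
ASN,CG,3
ASN,OD1,6
ASN,ND2,4
GLN,CD,3
GLN,OE1,6
GLN,NE2,4
ARG,CZ,3
ARG,NE,5
ARG,NH1,5
ARG,NH2,5
LYS,NZ,5
SER,OG,6
THR,OG1,6
CYS,SG,8
MET,SD,8
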