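residue,atom,charge,epsilon,rmin_half
GLY,N,-0.47,0.2,1.85
GLY,HN,0.31,0.046,0.2245
GLY,CA,-0.02,0.07,2
GLY,HA1,0.09,0.022,1.32
GLY,HA2,0.09,0.022,1.32
GLY,C,0.51,0.07,2
GLY,O,-0.51,0.12,1.7
ALA,N,-0.47,0.2,1.85
ALA,HN,0.31,0.046,0.2245
ALA,CA,0.07,0.07,2
ALA,HA,0.09,0.022,1.32
ALA,C,0.51,0.07,2
ALA,O,-0.51,0.12,1.7
ALA,CB,-0.27,0.07,2
ALA,HB1,0.09,0.022,1.32
ALA,HB2,0.09,0.022,1.32
ALA,HB3,0.09,0.022,1.32
SER,N,-0.47,0.2,1.85
SER,HN,0.31,0.046,0.2245
SER,CA,0.07,0.07,2
SER,HA,0.09,0.022,1.32
SER,C,0.51,0.07,2
SER,O,-0.51,0.12,1.7
SER,CB,0.05,0.07,2
SER,HB1,0.09,0.022,1.32
SER,HB2,0.09,0.022,1.32
SER,OG,-0.66,0.12,1.7
SER,HG1,0.43,0.046,0.2245
VAL,N,-0.47,0.2,1.85
VAL,HN,0.31,0.046,0.2245
VAL,CA,0.07,0.07,2
VAL,HA,0.09,0.022,1.32
VAL,C,0.51,0.07,2
VAL,O,-0.51,0.12,1.7
VAL,CB,-0.09,0.07,2
VAL,HB,0.09,0.022,1.32
VAL,CG1,-0.27,0.07,2
VAL,HG11,0.09,0.022,1.32
VAL,HG12,0.09,0.022,1.32
VAL,HG13,0.09,0.022,1.32
VAL,CG2,-0.27,0.07,2
VAL,HG21,0.09,0.022,1.32
VAL,HG22,0.09,0.022,1.32
VAL,HG23,0.09,0.022,1.32
CYS,N,-0.47,0.2,1.85
CYS,HN,0.31,0.046,0.2245
CYS,CA,0.07,0.07,2
CYS,HA,0.09,0.022,1.32
CYS,C,0.51,0.07,2
CYS,O,-0.51,0.12,1.7
CYS,CB,-0.11,0.07,2
CYS,HB1,0.09,0.022,1.32
CYS,HB2,0.09,0.022,1.32
CYS,SG,-0.23,0.45,2
CYS,HG1,0.16,0.1,0.45
ASP,N,-0.47,0.2,1.85
ASP,HN,0.31,0.046,0.2245
ASP,CA,0.07,0.07,2
ASP,HA,0.09,0.022,1.32
ASP,C,0.51,0.07,2
ASP,O,-0.51,0.12,1.7
ASP,CB,-0.28,0.07,2
ASP,HB1,0.09,0.022,1.32
ASP,HB2,0.09,0.022,1.32
ASP,CG,0.62,0.07,2
ASP,OD1,-0.76,0.12,1.7
ASP,OD2,-0.76,0.12,1.7
LYS,N,-0.47,0.2,1.85
LYS,HN,0.31,0.046,0.2245
LYS,CA,0.07,0.07,2
LYS,HA,0.09,0.022,1.32
LYS,C,0.51,0.07,2
LYS,O,-0.51,0.12,1.7
LYS,CB,-0.18,0.07,2
LYS,HB1,0.09,0.022,1.32
LYS,HB2,0.09,0.022,1.32
LYS,CG,-0.18,0.07,2
LYS,HG1,0.09,0.022,1.32
LYS,HG2,0.09,0.022,1.32
LYS,CD,-0.18,0.07,2
LYS,HD1,0.09,0.022,1.32
LYS,HD2,0.09,0.022,1.32
LYS,CE,0.21,0.07,2
LYS,HE1,0.05,0.022,1.32
LYS,HE2,0.05,0.022,1.32
LYS,NZ,-0.3,0.2,1.85
LYS,HZ1,0.33,0.046,0.2245
LYS,HZ2,0.33,0.046,0.2245
LYS,HZ3,0.33,0.046,0.2245
PHE,N,-0.47,0.2,1.85
PHE,HN,0.31,0.046,0.2245
PHE,CA,0.07,0.07,2
PHE,HA,0.09,0.022,1.32
PHE,C,0.51,0.07,2
PHE,O,-0.51,0.12,1.7
PHE,CB,-0.18,0.07,2
PHE,HB1,0.09,0.022,1.32
PHE,HB2,0.09,0.022,1.32
PHE,CG,0,0.07,2
PHE,CD1,-0.115,0.07,2
PHE,HD1,0.115,0.022,1.32
PHE,CD2,-0.115,0.07,2
PHE,HD2,0.115,0.022,1.32
PHE,CE1,-0.115,0.07,2
PHE,HE1,0.115,0.022,1.32
PHE,CE2,-0.115,0.07,2
PHE,HE2,0.115,0.022,1.32
PHE,CZ,-0.115,0.07,2
PHE,HZ,0.115,0.022,1.32
AMX,O1,-0.65,0.12,1.7
AMX,HO1,0.43,0.046,0.2245
AMX,C1,0.04,0.07,2
AMX,H11,0.09,0.022,1.32
AMX,H12,0.09,0.022,1.32
AMX,C2,0.13,0.07,2
AMX,H21,0.09,0.022,1.32
AMX,H22,0.09,0.022,1.32
AMX,N1,-0.3,0.2,1.85
AMX,HN1,0.33,0.046,0.2245
AMX,HN2,0.33,0.046,0.2245
AMX,HN3,0.33,0.046,0.2245
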