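# Acyclic substituent menu for scaffold decoration; entry k attaches via
# its final atom when prefixed to a scaffold SMILES. Empty line = bare.
C
CC
CCC
CCCC
CCCCC
CCCCCC
CC(C)
CC(C)(C)
CCC(C)
CC(C)C
CCCC(C)
CCCCC(C)
O
OC
OCC
OCCC
CO
CCO
COC
CCOC
OCCO
N
NC
NCC
CN
CCN
CN(C)
F
Cl
Br
I
FC
ClC
BrC
FC(F)
FC(F)(F)
N#C
O=C
O=C(C)
O=C(O)
O=C(N)
O=C(OC)
S
SC
CS
O=S(=O)(C)
O=[N+]([O-])
OCC(C)
CC(O)
CC(N)
CCCO
CCCN
COCC
CCOCC
CC(F)
NCCO
CN(C)CC
OCCCC
CCCCO
NCCC
OCCN
CCOCC(C)
COCCO
CC(C)CC
CC(C)O
CC(C)N
OC(C)C
CCC(O)
CCC(N)
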