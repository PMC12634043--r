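; Demonstration atomistic force field: reduced amino-acid set (heavy atoms,
; plus the His ring hydrogens that distinguish tautomers), a PEO repeat
; unit, and linear/branched polyethylene repeat units.

[ variables ]
backbone N CA C O
bb_bead BB
nter_mod N-ter
cter_mod C-ter

[ aliases ]
; input resname -> canonical block [+ pre-applied modifications]
HSE HIS
HSD HISD
HSP HIS HIS-protonated
HIP HIS HIS-protonated
PTR TYR TYR-phospho

[ block ]
name GLY
citation demo-aa-2024
[ atoms ]
N  N - -
CA C - -
C  C - -
O  O - -
[ bonds ]
N CA
CA C
C O

[ block ]
name ALA
citation demo-aa-2024
[ atoms ]
N  N - -
CA C - -
C  C - -
O  O - -
CB C - -
[ bonds ]
N CA
CA C
C O
CA CB

[ block ]
name CYS
citation demo-aa-2024
[ atoms ]
N  N - -
CA C - -
C  C - -
O  O - -
CB C - -
SG S - -
[ bonds ]
N CA
CA C
C O
CA CB
CB SG

[ block ]
name HIS
; epsilon tautomer: ring proton on NE2
citation demo-aa-2024
[ atoms ]
N   N - -
CA  C - -
C   C - -
O   O - -
CB  C - -
CG  C - -
ND1 N - -
CD2 C - -
CE1 C - -
NE2 N - -
HE2 H - -
[ bonds ]
N CA
CA C
C O
CA CB
CB CG
CG ND1
CG CD2
ND1 CE1
CD2 NE2
CE1 NE2
NE2 HE2

[ block ]
name HISD
; delta tautomer: ring proton on ND1
citation demo-aa-2024
[ atoms ]
N   N - -
CA  C - -
C   C - -
O   O - -
CB  C - -
CG  C - -
ND1 N - -
CD2 C - -
CE1 C - -
NE2 N - -
HD1 H - -
[ bonds ]
N CA
CA C
C O
CA CB
CB CG
CG ND1
CG CD2
ND1 CE1
CD2 NE2
CE1 NE2
ND1 HD1

[ block ]
name TYR
citation demo-aa-2024
[ atoms ]
N   N - -
CA  C - -
C   C - -
O   O - -
CB  C - -
CG  C - -
CD1 C - -
CD2 C - -
CE1 C - -
CE2 C - -
CZ  C - -
OH  O - -
[ bonds ]
N CA
CA C
C O
CA CB
CB CG
CG CD1
CG CD2
CD1 CE1
CD2 CE2
CE1 CZ
CE2 CZ
CZ OH

[ block ]
name PEO
citation demo-peo-2024
[ atoms ]
C1 C - -
C2 C - -
O1 O - -
[ bonds ]
C1 C2
C2 O1

[ block ]
name PEL
citation demo-pe-2024
[ atoms ]
C1 C - -
C2 C - -
[ bonds ]
C1 C2

[ block ]
name PEB
citation demo-pe-2024
[ atoms ]
C1  C - -
C2  C - -
CB1 C - -
CB2 C - -
[ bonds ]
C1 C2
C2 CB1
CB1 CB2

; sequential backbone connectivity (used by name-based bond inference)
[ link ]
[ atoms ]
1  0 C  GLY,ALA,CYS,HIS,HISD,TYR *
2 +1 N  GLY,ALA,CYS,HIS,HISD,TYR *
[ edges ]
1 2
[ bonds ]
1 2

[ link ]
[ atoms ]
1  0 O1 PEO *
2 +1 C1 PEO *
[ edges ]
1 2
[ bonds ]
1 2

[ link ]
[ atoms ]
1  0 C2 PEL,PEB *
2 +1 C1 PEL,PEB *
[ edges ]
1 2
[ bonds ]
1 2

[ modification ]
name HIS-protonated
resname HIS
citation demo-his-2024
[ atoms ]
ND1 N anchor
HD1 H added
[ edges ]
ND1 HD1
[ bead-edits ]
SC2 particle_type SQd
SC2 charge 1.0
[ mapping ]
HD1 SC2 0

[ modification ]
name TYR-phospho
resname TYR
citation demo-ptm-2024
[ atoms ]
OH  O anchor
P   P added
O1P O added
O2P O added
O3P O added
[ edges ]
OH P
P O1P
P O2P
P O3P
[ bead-edits ]
SC3 particle_type Qa
SC3 charge -2.0
[ mapping ]
P 	SC3 1
O1P SC3 1
O2P SC3 1
O3P SC3 1

[ modification ]
name N-ter
resname *
[ atoms ]
N N anchor
[ bead-edits ]
BB particle_type Qd
BB charge 1.0

[ modification ]
name C-ter
resname *
[ atoms ]
C C anchor
[ bead-edits ]
BB particle_type Qa
BB charge -1.0
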