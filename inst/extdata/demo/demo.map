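; Backwards-style mappings between the demo-aa and demo-cg force fields.
; Atom lines: index atom-name bead [bead ...] [weight]; a shared atom's
; unit weight is split equally over the listed beads; hydrogens default to
; weight 0.

[ molecule ]
GLY
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
BB
[ atoms ]
1 N  BB
2 CA BB
3 C  BB
4 O  BB

[ molecule ]
ALA
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
BB
[ atoms ]
1 N  BB
2 CA BB
3 C  BB
4 O  BB
5 CB BB

[ molecule ]
CYS
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
BB SC1
[ atoms ]
1 N  BB
2 CA BB
3 C  BB
4 O  BB
5 CB SC1
6 SG SC1

[ molecule ]
HIS
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
BB SC1 SC2 SC3
[ atoms ]
1  N   BB
2  CA  BB
3  C   BB
4  O   BB
5  CB  SC1
6  CG  SC1
7  ND1 SC2
8  CE1 SC2
9  CD2 SC3
10 NE2 SC3
11 HE2 SC3

[ molecule ]
HISD
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
BB SC1 SC2 SC3
[ atoms ]
1  N   BB
2  CA  BB
3  C   BB
4  O   BB
5  CB  SC1
6  CG  SC1
7  ND1 SC2
8  CE1 SC2
9  CD2 SC3
10 NE2 SC3
11 HD1 SC2

[ molecule ]
TYR
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
BB SC1 SC2 SC3
[ atoms ]
1  N   BB
2  CA  BB
3  C   BB
4  O   BB
5  CB  SC1
6  CG  SC1
7  CD1 SC2
8  CE1 SC2
9  CD2 SC3
10 CE2 SC3
11 CZ  SC2 SC3
12 OH  SC2 SC3

[ molecule ]
PEO
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
EO
[ atoms ]
1 C1 EO
2 C2 EO
3 O1 EO

[ molecule ]
PEL
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
CM
[ atoms ]
1 C1 CM
2 C2 CM

[ molecule ]
PEB
[ from ]
demo-aa
[ to ]
demo-cg
[ martini ]
CM CBR
[ atoms ]
1 C1  CM
2 C2  CM
3 CB1 CBR
4 CB2 CBR
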