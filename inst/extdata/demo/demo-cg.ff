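; Demonstration coarse-grained force field (Martini-style bead sizes:
; roughly 2-5 heavy atoms per bead).  Particle types and bonded parameters
; are illustrative, not a published parameter set.

[ variables ]
bb_bead BB

[ block ]
name GLY
nrexcl 1
citation demo-cg-2024
[ atoms ]
BB - P5 0.0 72.0

[ block ]
name ALA
nrexcl 1
citation demo-cg-2024
[ atoms ]
BB - P4 0.0 72.0

[ block ]
name CYS
nrexcl 1
citation demo-cg-2024
[ atoms ]
BB  - P5 0.0 72.0
SC1 - C5 0.0 45.0
[ bonds ]
BB SC1 1 0.310 7500

[ block ]
name HIS
nrexcl 1
citation demo-cg-2024
[ atoms ]
BB  - P5   0.0 72.0
SC1 - SC4  0.0 45.0
SC2 - TN6d 0.0 45.0
SC3 - TN5a 0.0 45.0
[ bonds ]
BB SC1 1 0.320 7500
[ constraints ]
SC1 SC2 1 0.300
SC1 SC3 1 0.300
SC2 SC3 1 0.270

[ block ]
name HISD
nrexcl 1
citation demo-cg-2024
[ atoms ]
BB  - P5   0.0 72.0
SC1 - SC4  0.0 45.0
SC2 - TN5a 0.0 45.0
SC3 - TN6d 0.0 45.0
[ bonds ]
BB SC1 1 0.320 7500
[ constraints ]
SC1 SC2 1 0.300
SC1 SC3 1 0.300
SC2 SC3 1 0.270

[ block ]
name TYR
nrexcl 1
citation demo-cg-2024
[ atoms ]
BB  - P5  0.0 72.0
SC1 - TC4 0.0 45.0
SC2 - TC5 0.0 45.0
SC3 - TN6 0.0 45.0
[ bonds ]
BB SC1 1 0.320 7500
[ constraints ]
SC1 SC2 1 0.300
SC1 SC3 1 0.300
SC2 SC3 1 0.290

[ block ]
name PEO
nrexcl 1
citation demo-peo-2024
[ atoms ]
EO - EO 0.0 44.0

[ block ]
name PEL
nrexcl 1
citation demo-pe-2024
[ atoms ]
CM - C1 0.0 28.0

[ block ]
name PEB
nrexcl 1
citation demo-pe-2024
[ atoms ]
CM  - C1 0.0 28.0
CBR - C2 0.0 28.0
[ bonds ]
CM CBR 1 0.260 5000

; backbone bond between bonded BB beads (edge based, so cyclic molecules
; and chain breaks are handled by the graph, not residue numbering)
[ link ]
[ atoms ]
1 ? BB * *
2 ? BB * *
[ edges ]
1 2
[ bonds ]
1 2 1 0.350 1250

; generic backbone angle
[ link ]
[ atoms ]
1 ? BB * *
2 ? BB * *
3 ? BB * *
[ edges ]
1 2
2 3
[ angles ]
1 2 3 2 127 20

; helical backbone angle overrides the generic one (file order = precedence)
[ link ]
[ atoms ]
1 ? BB * H
2 ? BB * H
3 ? BB * H
[ edges ]
1 2
2 3
[ angles ]
1 2 3 2 96 700

; disulfide bridge between cysteine side-chain beads
[ link ]
citation demo-ss-2024
[ atoms ]
1 ? SC1 CYS *
2 ? SC1 CYS *
[ edges ]
1 2
[ bonds ]
1 2 1 0.240 5000

[ link ]
[ atoms ]
1 ? EO PEO *
2 ? EO PEO *
[ edges ]
1 2
[ bonds ]
1 2 1 0.322 7000

[ link ]
[ atoms ]
1 ? EO PEO *
2 ? EO PEO *
3 ? EO PEO *
[ edges ]
1 2
2 3
[ angles ]
1 2 3 2 135 50

[ link ]
[ atoms ]
1 ? CM PEL,PEB *
2 ? CM PEL,PEB *
[ edges ]
1 2
[ bonds ]
1 2 1 0.280 8000
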