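# lysine: unbranched, positively charged control; four chi torsions
[atoms]
N   N 0  -  -  -  -     -     -
CA  C 0  -  -  -  -     -     -
C   C 0  -  -  -  -     -     -
O   O 0  -  -  -  -     -     -
CB  C 0  C  N  CA 1.530 110.5 -122.0
CG  C 0  N  CA CB 1.520 114.0 chi1
CD  C 0  CA CB CG 1.520 111.0 chi2
CE  C 0  CB CG CD 1.520 111.0 chi3
NZ  N 1  CG CD CE 1.490 111.0 chi4
HZ1 H 0  CD CE NZ 1.010 109.5 60
HZ2 H 0  CD CE NZ 1.010 109.5 180
HZ3 H 0  CD CE NZ 1.010 109.5 -60
[bonds]
N CA
CA C
C O
CA CB
CB CG
CG CD
CD CE
CE NZ
NZ HZ1
NZ HZ2
NZ HZ3
[chi]
N CA CB CG
CA CB CG CD
CB CG CD CE
CG CD CE NZ
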