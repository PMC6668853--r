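# beta-methylamino-L-alanine: CB-NG(H2+)-CD(methyl) side chain,
# protonated secondary amine -> net +1; two chi torsions
[atoms]
N   N 0  -  -  -  -     -     -
CA  C 0  -  -  -  -     -     -
C   C 0  -  -  -  -     -     -
O   O 0  -  -  -  -     -     -
CB  C 0  C  N  CA 1.530 110.5 -122.0
NG  N 1  N  CA CB 1.470 109.5 chi1
CD  C 0  CA CB NG 1.470 109.5 chi2
HG1 H 0  CB NG CD 1.010 109.5 120
HG2 H 0  CB NG CD 1.010 109.5 -120
[bonds]
N CA
CA C
C O
CA CB
CB NG
NG CD
NG HG1
NG HG2
[chi]
N CA CB NG
CA CB NG CD
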