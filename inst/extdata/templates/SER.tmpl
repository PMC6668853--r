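# serine: polar-hydrogen model (heavy atoms + HG)
[atoms]
N  N 0  -  -  -  -     -     -
CA C 0  -  -  -  -     -     -
C  C 0  -  -  -  -     -     -
O  O 0  -  -  -  -     -     -
CB C 0  C  N  CA 1.530 110.5 -122.0
OG O 0  N  CA CB 1.417 110.8 chi1
HG H 0  CA CB OG 0.960 109.5 180
[bonds]
N CA
CA C
C O
CA CB
CB OG
OG HG
[chi]
N CA CB OG
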