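# 2,3-diaminopropionic acid: the demethylated analogue of BMAA --
# same protonated beta-amine (+1), one chi torsion, minimal bulk.
# Serves as the conservative same-charge control in stability scans.
[atoms]
N   N 0  -  -  -  -     -     -
CA  C 0  -  -  -  -     -     -
C   C 0  -  -  -  -     -     -
O   O 0  -  -  -  -     -     -
CB  C 0  C  N  CA 1.530 110.5 -122.0
NG  N 1  N  CA CB 1.470 109.5 chi1
HG1 H 0  CA CB NG 1.010 109.5 60
HG2 H 0  CA CB NG 1.010 109.5 180
HG3 H 0  CA CB NG 1.010 109.5 -60
[bonds]
N CA
CA C
C O
CA CB
CB NG
NG HG1
NG HG2
NG HG3
[chi]
N CA CB NG
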