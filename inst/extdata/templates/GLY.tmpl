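# glycine: backbone only
[atoms]
N  N 0  -  -  -  -  -  -
CA C 0  -  -  -  -  -  -
C  C 0  -  -  -  -  -  -
O  O 0  -  -  -  -  -  -
[bonds]
N CA
CA C
C O
[chi]
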