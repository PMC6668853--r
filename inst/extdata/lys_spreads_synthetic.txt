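# Synthetic surrogate spread table for lysine-like side chains.
# Representative chi-angle standard deviations (degrees) and a
# reference energy (kcal/mol); constructed values, not extracted from
# any published rotamer library.
chi sd reference_energy
1 9.5 -0.75
2 10.5 -0.75
3 11.0 -0.75
4 12.5 -0.75
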