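conc_M	V_monomer	V_dimer
2e-05	16.9813	4.96111
1e-04	50.1267	47.659
5e-04	137.823	358.512
0.001	183.569	800.095
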