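conc_M	V_monomer	V_dimer
2e-05	14.7472	4.29268
1e-04	51.283	48.4783
5e-04	144.71	360.536
0.001	227.852	755.126
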