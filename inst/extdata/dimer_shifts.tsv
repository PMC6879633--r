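residue	dH_major	dN_major	dH_minor	dN_minor
W43e	10.05	129.2	9.73	128.6
T17	8.41	112.6	8.33	112
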