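residue	dH_major	dN_major	dH_minor	dN_minor
W43e	10.12	129.5	9.02	127.3
T17	8.43	112.7	8.36	112.1
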