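"temperature_C","ellipticity_mdeg"
25,-12.2488
27,-12.2689
29,-12.3381
31,-12.333
33,-12.3611
35,-12.3888
37,-12.4196
39,-12.3957
41,-12.3673
43,-12.3071
45,-12.4395
47,-12.4139
49,-12.3835
51,-12.3366
53,-12.2734
55,-12.1641
57,-12.0264
59,-11.9196
61,-11.5671
63,-11.1154
65,-10.6504
67,-10.0393
69,-9.39011
71,-8.64027
73,-7.78764
75,-7.1284
77,-6.49871
79,-6.07083
81,-5.79251
83,-5.48482
85,-5.35696
87,-5.12572
89,-5.02675
91,-5.01031
93,-5.03048
95,-4.92139
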