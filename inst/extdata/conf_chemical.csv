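"conc_M","fraction_unfolded"
0,-0.0154945
0.454545454545455,0.00383483
0.909090909090909,0.062499
1.36363636363636,0.246142
1.81818181818182,0.578002
2.27272727272727,0.877955
2.72727272727273,0.951425
3.18181818181818,1.01885
3.63636363636364,1.0405
4.09090909090909,1.00702
4.54545454545454,0.956979
5,1.00941
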