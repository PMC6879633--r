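"conc_M","fraction_unfolded"
0,0.0319465
0.454545454545455,0.0942497
0.909090909090909,0.341955
1.36363636363636,0.819745
1.81818181818182,0.966884
2.27272727272727,0.967109
2.72727272727273,1.0014
3.18181818181818,1.00614
3.63636363636364,0.98461
4.09090909090909,1.00257
4.54545454545454,1.00487
5,1.00861
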