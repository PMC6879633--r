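residue	direction	temperature_K	k_per_s
W43e	1->2	282.15	1.40706
W43e	1->2	287.15	1.77009
W43e	1->2	292.15	2.2958
W43e	1->2	297.15	2.72447
W43e	1->2	302.15	3.45147
W43e	2->1	282.15	2.22709
W43e	2->1	287.15	3.10182
W43e	2->1	292.15	4.1998
W43e	2->1	297.15	5.52646
W43e	2->1	302.15	7.46943
T17	1->2	282.15	1.44614
T17	1->2	287.15	1.90249
T17	1->2	292.15	2.41052
T17	1->2	297.15	3.10104
T17	1->2	302.15	3.68713
T17	2->1	282.15	2.40469
T17	2->1	287.15	2.98796
T17	2->1	292.15	4.55142
T17	2->1	297.15	6.00172
T17	2->1	302.15	7.73598
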