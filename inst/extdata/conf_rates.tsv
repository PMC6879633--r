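residue	direction	temperature_K	k_per_s
W43e	1->2	282.15	0.836914
W43e	1->2	287.15	1.13635
W43e	1->2	292.15	1.43466
W43e	1->2	297.15	1.91259
W43e	1->2	302.15	2.46839
W43e	2->1	282.15	2.02826
W43e	2->1	287.15	2.01836
W43e	2->1	292.15	1.75418
W43e	2->1	297.15	1.73969
W43e	2->1	302.15	1.49898
T17	1->2	282.15	0.749692
T17	1->2	287.15	0.955536
T17	1->2	292.15	1.13615
T17	1->2	297.15	1.43431
T17	1->2	302.15	1.65851
T17	2->1	282.15	1.56911
T17	2->1	287.15	2.34527
T17	2->1	292.15	3.36287
T17	2->1	297.15	4.62697
T17	2->1	302.15	6.74838
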