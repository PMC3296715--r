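species	interruptionEvents	interruptionNumts	deletionEvents	deletionNumts	inversionEvents	inversionNumts	duplicationEvents	duplicationNumts
Dmel	0	0	0	0	0	0	0	0
Dsim	0	0	0	0	0	0	0	0
Dsec	2	2	1	1	1	1	0	0
Dyak	4	2	5	3	0	0	1	1
Dere	0	0	4	2	0	0	0	0
Dana	5	5	0	0	0	0	0	0
Dper	0	0	5	4	2	2	1	1
Dwil	21	8	12	7	1	1	4	4
Dmoj	12	6	4	3	0	0	3	3
Dvir	15	8	16	11	2	2	9	5
Dgri	0	0	1	1	0	0	0	0
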