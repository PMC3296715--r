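species	genomeSizeMb	repeatPct	nNumts	avgLengthBp	totalContentBp
Dmel	118	5.35	4	210	838
Dsim	111	2.73	5	700	3501
Dsec	115	3.67	25	1502	37553
Dyak	127	12.04	9	1497	13471
Dere	134	6.97	20	1255	25103
Dana	176	24.93	26	1537	39952
Dper	138	8.47	54	1335	72107
Dwil	187	15.57	67	900	60284
Dmoj	172	13.96	24	3029	72689
Dvir	161	8.92	59	2506	147862
Dgri	138	2.84	9	2075	18673
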