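term	coef	sd	len_max	len_min
GATA417	1.59	0.38	252	223
EV037	0.40	0.52	211	203
GATA028	0.40	0.52	223	202
GT575	0.09	0.58	166	155
GT509	-0.35	0.68	217	203
GT310	-0.35	0.68	125	117
GT211	-0.35	0.68	116	106
GT023	-0.35	0.68	115	103
GATA098	-1.08	0.93	107	93
EV001	NA	NA	175	153
YEAR	-0.36	0.11	NA	NA
Intercept	-4.74	0.45	NA	NA
VAR_IND	1.81	0.94	NA	NA
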