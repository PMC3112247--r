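locus	p	sd	sd_warn0
GATA417	0.0774	0.0214	0.0241
EV037	0.0283	0.0112	0.0122
GATA028	0.0283	0.0130	0.0134
GT575	0.0213	0.0110	0.0112
GT509	0.0141	0.0093	0.0095
GT310	0.0141	0.0101	0.0102
GT211	0.0141	0.0083	0.0085
GT023	0.0141	0.0091	0.0092
GATA098	0.0071	0.0084	0.0084
EV001	0	0	NA
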