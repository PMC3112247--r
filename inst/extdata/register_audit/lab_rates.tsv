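lab	period	n_analyzed	n_sampled	p_l	sd_pl	p_a	sd_pa	pred
Lab1	1997-2002	116	120	0.02373	0.00443	0.01422	0.00246	0.02825
Lab2	2003-2005	60	60	0.00500	0.00288	0.00333	0.00166	0.00666
Lab3	2006	19	20	0	NA	0	NA	0
Lab4	2007-2008	39	40	0.00256	0.00256	0.00128	0.00128	0.00256
Total	1997-2008	234	240	0.01325	0.00236	0.00812	0.00131	0.01617
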