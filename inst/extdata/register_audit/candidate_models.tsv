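model	fixed	random	sigma	aic
M1	LOCUS+YEAR	IND	1.35	295.7
M2	YEAR	IND	1.24	297.5
M3	LAB+LOCUS	IND	1.43	299.3
M4	LAB	IND	1.32	301.0
M5	LOCUS+YEAR	-	NA	303.1
M6	LOCUS+YEAR	MP:IND	1.22	303.5
M7	YEAR	-	NA	303.6
M8	YEAR	MP:IND	1.13	304.0
M9	LAB+LOCUS	-	NA	307.1
M10	LAB+LOCUS	MP:IND	1.31	307.2
M11	LAB	-	NA	307.5
M12	LAB	MP:IND	1.20	307.9
M13	LOCUS	IND	1.52	308.3
M14	-	IND	1.41	309.9
M15	LOCUS	MP:IND	1.50	318.3
M16	-	MP:IND	1.36	319.1
M17	LOCUS	-	NA	319.5
M18	-	-	NA	319.8
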