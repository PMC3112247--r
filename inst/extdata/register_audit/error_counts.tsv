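lab	error_class	shift_class	n
Lab1	single_false_allele	eq_1bp	7
Lab1	single_false_allele	gt_1bp	3
Lab1	double_false_allele	eq_1bp	1
Lab1	double_false_allele	gt_1bp	5
Lab1	false_homozygote	eq_1bp	5
Lab1	false_homozygote	gt_1bp	4
Lab1	false_heterozygote	eq_1bp	0
Lab1	false_heterozygote	gt_1bp	2
Lab2	single_false_allele	eq_1bp	0
Lab2	single_false_allele	gt_1bp	2
Lab2	double_false_allele	eq_1bp	0
Lab2	double_false_allele	gt_1bp	0
Lab2	false_homozygote	eq_1bp	1
Lab2	false_homozygote	gt_1bp	0
Lab2	false_heterozygote	eq_1bp	0
Lab2	false_heterozygote	gt_1bp	0
Lab3	single_false_allele	eq_1bp	0
Lab3	single_false_allele	gt_1bp	0
Lab3	double_false_allele	eq_1bp	0
Lab3	double_false_allele	gt_1bp	0
Lab3	false_homozygote	eq_1bp	0
Lab3	false_homozygote	gt_1bp	0
Lab3	false_heterozygote	eq_1bp	0
Lab3	false_heterozygote	gt_1bp	0
Lab4	single_false_allele	eq_1bp	0
Lab4	single_false_allele	gt_1bp	0
Lab4	double_false_allele	eq_1bp	0
Lab4	double_false_allele	gt_1bp	0
Lab4	false_homozygote	eq_1bp	0
Lab4	false_homozygote	gt_1bp	0
Lab4	false_heterozygote	eq_1bp	0
Lab4	false_heterozygote	gt_1bp	1
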