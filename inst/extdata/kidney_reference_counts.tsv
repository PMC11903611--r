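measure	glomeruli_count	glomeruli_pct	tubules_count	tubules_pct
total	11157	NA	10108	NA
concordant	2682	24.04	3808	37.67
discordant	8475	75.96	6300	62.33
protein_null_rna_detected	4953	44.39	2122	20.99
protein_null_ntpm_strict	3773	33.46	1172	11.59
protein_null_ms_validated	637	5.71	171	1.69
rna_null_protein_detected	76	0.68	141	1.39
rna_null_ext_detected	62	0.56	120	1.19
rna_null_ext_strict	5	0.04	3	0.03
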