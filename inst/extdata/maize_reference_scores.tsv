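treatment	root_length_cm	shoot_length_cm	root_fw_g	shoot_fw_g	root_dw_g	shoot_dw_g	root_dry_biomass_pct	shoot_dry_biomass_pct	spad	shannon_bacteria	shannon_fungi	up_genes_21das	up_genes_60das	total	mean
Control	1	1	7	1	8	3	8	4	1	5	8	1	2	50	3.8
Char	2	7	2	4	8	3	4	1	4	2	7	7	8	59	4.5
AMF	6	4	7	6	4	6	3	6	2	7	5	6	7	69	5.3
Char_AMF	3	8	8	5	4	5	2	2	5	2	6	6	2	58	4.5
Char_MC-B	4	5	2	3	4	3	6	3	3	6	4	6	5	54	4.2
Char_MC-C	5	6	5	2	8	5	5	5	7	8	2	8	4	70	5.4
Char_MC-B_AMF	8	3	5	8	4	8	1	8	8	5	3	2	4	67	5.2
Char_MC-C_AMF	7	2	3	7	8	7	7	7	6	5	1	6	7	73	5.6
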