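treatment	root_length_cm	shoot_length_cm	root_fw_g	shoot_fw_g	root_dw_g	shoot_dw_g	root_dry_biomass_pct	shoot_dry_biomass_pct	spad	shannon_bacteria	shannon_fungi	up_genes_21das	up_genes_60das	total	mean
Control	10	7	8	4	8	1	3	7	5	2	4	1	1	61	4.7
Char	1	6	8	8	8	7	8	7	7	1	1	7	7	76	5.8
AMF	11	5	8	6	8	5	9	3	8	6	4	3	2	78	6.0
Char_AMF	4	3	2	4	8	9	5	12	3	6	2	5	4	67	5.2
MC-B	8	8	8	6	8	5	4	5	2	NA	NA	NA	NA	54	6.0
MC-C	2	1	4	4	8	2	3	10	4	6	7	7	5	63	4.8
MC-B_AMF	7	2	1	4	8	5	11	11	1	NA	NA	NA	NA	50	5.6
MC-C_AMF	3	5	9	8	8	7	1	5	6	6	7	8	8	81	6.2
Char_MC-B	6	9	11	12	10	12	7	2	10	NA	NA	NA	NA	79	8.8
Char_MC-C	5	11	12	9	12	10	6	9	12	8	5	5	7	111	8.5
Char_MC-B_AMF	9	10	11	11	12	11	10	8	11	NA	NA	NA	NA	93	10.3
Char_MC-C_AMF	12	12	4	10	10	8	12	1	9	7	8	3	4	100	7.7
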