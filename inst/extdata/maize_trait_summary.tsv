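treatment	root_length_cm	shoot_length_cm	root_fw_g	shoot_fw_g	root_dw_g	shoot_dw_g	root_dry_biomass_pct	shoot_dry_biomass_pct	spad	sd_root_length_cm	sd_shoot_length_cm	sd_root_fw_g	sd_shoot_fw_g	sd_root_dw_g	sd_shoot_dw_g	sd_root_dry_biomass_pct	sd_shoot_dry_biomass_pct	sd_spad
Control	51.7	56.0	3.1	4.3	0.3	0.6	10.3	14.5	9.4	10.3	8.0	0.7	1.7	0.1	0.2	1.2	1.4	2.4
Char	59.2	68.0	2.6	5.0	0.3	0.6	9.0	12.0	13.0	16.6	10.9	0.5	3.3	0.6	0.3	1.0	0.9	2.6
AMF	70.8	62.8	3.1	6.6	0.2	1.1	8.7	15.4	12.2	9.3	13.8	1.1	2.9	0.1	0.7	3.0	2.7	1.8
Char_AMF	61.2	68.3	3.2	5.3	0.2	0.7	8.4	13.0	13.4	10.5	20.0	1.7	2.4	0.1	0.3	1.9	1.3	3.4
Char_MC-B	61.7	64.5	2.6	4.8	0.2	0.6	9.2	14.3	12.5	13.0	14.5	0.4	2.0	0.1	0.3	0.7	0.1	2.3
Char_MC-C	65.2	65.2	3.0	4.7	0.3	0.7	9.1	14.6	15.0	7.0	9.1	0.4	1.8	0.1	0.3	1.3	2.2	3.7
Char_MC-B_AMF	88.2	62.2	3.0	12.5	0.2	2.7	8.1	22.3	17.5	21.5	9.6	0.9	6.4	0.1	0.1	1.2	8.7	3.8
Char_MC-C_AMF	81.0	59.7	2.7	8.9	0.3	1.5	9.5	16.1	14.5	10.3	11.8	1.0	3.1	0.1	0.6	1.1	1.9	3.4
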