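treatment	root_length_cm	shoot_length_cm	root_fw_g	shoot_fw_g	root_dw_g	shoot_dw_g	root_dry_biomass_pct	shoot_dry_biomass_pct	spad	sd_root_length_cm	sd_shoot_length_cm	sd_root_fw_g	sd_shoot_fw_g	sd_root_dw_g	sd_shoot_dw_g	sd_root_dry_biomass_pct	sd_shoot_dry_biomass_pct	sd_spad
Control	61.2	33.3	0.7	0.4	0.1	0.12	11.4	28.1	25.8	6.7	2.6	0.1	0.1	0.1	0.02	3.4	2.7	2.2
Char	26.2	32.0	0.7	0.6	0.1	0.16	15.5	28.1	27.2	2.3	5.1	0.3	0.1	0.0	0.03	6.1	6.2	2.3
AMF	64.6	31.8	0.7	0.5	0.1	0.15	15.7	26.7	27.7	9.0	4.3	0.1	0.1	0.0	0.04	3.2	13.3	1.6
Char_AMF	44.4	30.0	0.5	0.4	0.1	0.31	14.6	37.9	24.1	3.4	3.7	0.1	0.1	0.0	0.03	3.2	10.8	3.5
MC-B	53.6	35.4	0.7	0.5	0.1	0.15	12.5	27.2	23.6	24.8	4.7	0.2	0.1	0.0	0.01	1.0	4.3	1.6
MC-C	35.6	27.8	0.6	0.4	0.1	0.14	11.4	30.8	24.2	17.2	1.3	0.1	0.1	0.0	0.01	5.1	7.6	2.1
MC-B_AMF	52.6	28.4	0.4	0.4	0.1	0.15	18.5	31.4	22.2	8.1	5.7	0.2	0.1	0.0	0.01	6.8	4.6	5.2
MC-C_AMF	39.4	31.6	1.5	0.6	0.1	0.16	9.9	27.2	26.2	3.3	5.3	0.5	0.1	0.1	0.04	10.6	8.2	3.3
Char_MC-B	49.2	45.0	1.6	1.9	0.2	0.47	15.2	24.1	29.0	9.4	7.3	0.5	0.1	0.1	0.07	7.8	2.2	4.1
Char_MC-C	48.6	45.6	2.0	1.4	0.3	0.42	14.7	30.6	33.3	10.0	3.3	0.7	0.4	0.1	0.02	3.7	8.4	8.7
Char_MC-B_AMF	54.8	45.4	1.6	1.7	0.3	0.44	17.3	28.4	29.5	3.3	11.5	0.3	0.1	0.1	0.02	3.0	3.0	1.5
Char_MC-C_AMF	74.8	48.2	0.6	1.5	0.2	0.22	26.4	16.0	27.8	7.0	3.3	0.1	0.3	0.0	0.06	6.7	6.1	3.0
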