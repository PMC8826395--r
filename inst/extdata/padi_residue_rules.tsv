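name	positions	kind	ai_states	bi_states	severity
ca_switch_D389	389	diagnostic	D	G	critical
ca_site6_D125	125	diagnostic	D	N	critical
ca_site6_E131	131	diagnostic	E	D	critical
connector_triple_his_300_302	300,301,302	diagnostic	!,!,!	H,H,H	critical
catalytic_D351	351	conserved	D		critical
catalytic_H471	471	conserved	H		critical
catalytic_D473	473	conserved	D		critical
catalytic_C647	647	conserved	C		critical
bi_diagnostic_region_155_180	155-180	region			advisory
connector_beta_sheet_292_302	292-302	region			advisory
ca_switch_region_369_389	369-389	region			advisory
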