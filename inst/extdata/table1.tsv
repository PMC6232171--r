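sample_id	genotype	entity	cgr_chroms	mycn_gain	myc_gain
630	XRCC4/p53	MB		TRUE	TRUE
1187	XRCC4/p53	MB		TRUE	FALSE
1197	XRCC4/p53	MB		TRUE	FALSE
506	XRCC4/p53	MB		TRUE	FALSE
1206	XRCC4/p53	MB	chr6,chr13	FALSE	FALSE
1207	XRCC4/p53	MB	chr7	TRUE	FALSE
1224	XRCC4/p53	MB	chr15	TRUE	TRUE
706	XRCC4/p53	MB	chr7	TRUE	FALSE
794	XRCC4/p53	MB	chr15	TRUE	TRUE
594	XRCC4/p53	MB	chr12	TRUE	FALSE
NXP005	XRCC4/p53	MB	chr13,chr15	FALSE	TRUE
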