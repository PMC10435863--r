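"block","arm","parameter","value","low","high","distribution","basis"
"probability","PP1M","p_disc_nonstable",0.214,0.1926,0.2354,"beta",NA
"probability","PP1M","p_disc_stable",0.0483,0.0435,0.0531,"beta",NA
"probability","PP1M","p_relapse_stable",0.0292,0.0263,0.0321,"beta",NA
"probability","PP1M","p_relapse_nonadherent",0.4731,0.4258,0.5204,"beta",NA
"probability","PP1M","p_hosp_nonstable",0.0102,0.0091,0.0112,"beta",NA
"cost","PP1M","drug_cost_cycle_stable",958.87,767.1,1150.65,"gamma","per_cycle"
"cost","PP1M","drug_cost_cycle_nonstable",958.87,767.1,1150.65,"gamma","per_cycle"
"probability","PP3M","p_disc_nonstable",0.214,0.1926,0.2354,"beta",NA
"probability","PP3M","p_disc_stable",0.0434,0.0391,0.0477,"beta",NA
"probability","PP3M","p_relapse_stable",0.024,0.0216,0.0264,"beta",NA
"probability","PP3M","p_relapse_nonadherent",0.3465,0.3119,0.3812,"beta",NA
"probability","PP3M","p_hosp_nonstable",0.0076,0.0071,0.0083,"beta",NA
"cost","PP3M","drug_cost_cycle_stable",813.64,650.91,976.36,"gamma","per_cycle"
"cost","PP3M","drug_cost_cycle_nonstable",958.87,767.1,1150.65,"gamma","per_cycle"
"probability","ER","p_disc_nonstable",0.2831,0.2548,0.3114,"beta",NA
"probability","ER","p_disc_stable",0.1792,0.1613,0.1971,"beta",NA
"probability","ER","p_relapse_stable",0.2655,0.239,0.2921,"beta",NA
"probability","ER","p_relapse_nonadherent",0.9864,0.8878,1,"beta",NA
"probability","ER","p_hosp_nonstable",0.0503,0.0453,0.0554,"beta",NA
"cost","ER","drug_cost_cycle_stable",759.09,607.27,910.91,"gamma","per_cycle"
"cost","ER","drug_cost_cycle_nonstable",759.09,607.27,910.91,"gamma","per_cycle"
"utility",NA,"stable",0.23,0.21,0.25,"beta",NA
"utility",NA,"non_stable",0.15,0.14,0.17,"beta",NA
"utility",NA,"relapse",0.15,0.14,0.17,"beta",NA
"cost",NA,"hospitalization",1998.9,1599.12,2398.68,"gamma","per_admission"
"cost",NA,"outpatient_stable",127.52,102.02,153.03,"gamma","per_cycle"
"cost",NA,"outpatient_nonstable",183.3,164.97,219.96,"gamma","per_cycle"
"mortality",NA,"age_35_39",0.006267,NA,NA,"fixed",NA
"mortality",NA,"age_40_44",0.004904,NA,NA,"fixed",NA
"mortality",NA,"age_45_49",0.007708,NA,NA,"fixed",NA
"mortality",NA,"age_50_54",0.007606,NA,NA,"fixed",NA
"mortality",NA,"age_55_59",0.011745,NA,NA,"fixed",NA
"mortality",NA,"age_60_64",0.03561,NA,NA,"fixed",NA
"mortality",NA,"age_65_78",0.016676,NA,NA,"fixed",NA
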