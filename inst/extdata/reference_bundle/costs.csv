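item,age_low,age_high,value,lower,upper,distribution,provenance
intervention_base,NA,NA,228,NA,NA,gamma,fixture
intervention_diet,NA,NA,177,NA,NA,gamma,synthetic
intervention_pa,NA,NA,197,NA,NA,gamma,synthetic
intervention_diet_pa,NA,NA,228,NA,NA,gamma,synthetic
antenatal_gdm,NA,NA,1840,NA,NA,gamma,synthetic
caesarean_cost,NA,NA,13950,NA,NA,gamma,synthetic
induction_cost,NA,NA,6800,NA,NA,gamma,synthetic
p_caesarean_gdm,NA,NA,0.4,NA,NA,beta,fixture
p_caesarean_no_gdm,NA,NA,0.33,NA,NA,beta,synthetic
p_induction_gdm,NA,NA,0.44,NA,NA,beta,fixture
p_induction_no_gdm,NA,NA,0.3,NA,NA,beta,synthetic
p_nicu_gdm,NA,NA,0.384,NA,NA,beta,synthetic
p_nicu_no_gdm,NA,NA,0.213,NA,NA,beta,synthetic
nicu_cost,NA,NA,16950,NA,NA,gamma,synthetic
t2dm_annual_cost,15,49,1250,NA,NA,gamma,synthetic
t2dm_annual_cost,50,59,1550,NA,NA,gamma,synthetic
t2dm_annual_cost,60,69,1850,NA,NA,gamma,synthetic
t2dm_annual_cost,70,110,2100,NA,NA,gamma,synthetic
microcost_first_year,NA,NA,4800,NA,NA,gamma,synthetic
microcost_subsequent_year,NA,NA,4000,NA,NA,gamma,synthetic
microcost_direct_nonhealth,NA,NA,1500,NA,NA,gamma,synthetic
microcost_income_subsidy,NA,NA,7200,NA,NA,gamma,synthetic
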