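parameter,mean,lower,upper,distribution,provenance
rr_t2dm_after_gdm,9.51,7.14,12.67,lognormal,fixture
rr_gdm_base,0.67,0.58,0.77,lognormal,fixture
rr_gdm_diet,0.66,0.5,0.85,lognormal,fixture
rr_gdm_pa,0.62,0.5,0.77,lognormal,fixture
rr_gdm_diet_pa,0.75,0.58,0.97,lognormal,fixture
rr_t2dm_avoided_gdm,1,1,9.5,fixed,fixture
gdm_prevalence_population,0.0065,NA,NA,fixed,fixture
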