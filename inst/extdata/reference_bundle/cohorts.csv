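band_label,age_low,age_high,representative_age,n_births,gdm_prevalence,preexisting_dm_prevalence,provenance
15-19,15,19,17,8069,0.055,0.002,synthetic
20-24,20,24,22,40560,0.07,0.004,synthetic
25-29,25,29,27,84970,0.095,0.007,synthetic
30-34,30,34,32,104950,0.125,0.01,synthetic
35-39,35,39,37,54980,0.165,0.015,synthetic
40-44,40,44,42,12570,0.215,0.022,synthetic
45-49,45,49,47,500,0.26,0.03,synthetic
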