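band,age_low,age_high,mean,lower,upper,distribution,provenance
18-24,15,24,0.95,0.92,0.98,beta,fixture
25-34,25,34,0.95,0.9,0.99,beta,fixture
35-44,35,44,0.91,0.86,0.96,beta,fixture
45-54,45,54,0.87,0.81,0.93,beta,fixture
55-64,55,64,0.88,0.82,0.94,beta,fixture
65-74,65,74,0.87,0.8,0.94,beta,fixture
75+,75,110,0.82,0.74,0.9,beta,fixture
t2dm,NA,NA,0.785,0.68,0.89,beta,fixture
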