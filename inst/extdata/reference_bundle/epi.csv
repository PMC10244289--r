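age,t2dm_incidence_total,all_cause_mortality,t2dm_mortality,t2dm_prevalence,population,provenance
15,5.903e-5,1.6e-4,1.6e-4,9.33e-4,165000,synthetic
16,6.593e-5,1.6578e-4,1.6578e-4,0.00103,165000,synthetic
17,7.362e-5,1.7212e-4,1.7212e-4,0.001138,165000,synthetic
18,8.221e-5,1.7907e-4,1.7907e-4,0.001257,165000,synthetic
19,9.179e-5,1.8669e-4,1.8669e-4,0.001388,165000,synthetic
20,1.0248e-4,1.9504e-4,1.9504e-4,0.001532,165000,synthetic
21,1.1439e-4,2.042e-4,2.042e-4,0.001692,165000,synthetic
22,1.2768e-4,2.1424e-4,2.1424e-4,0.001868,165000,synthetic
23,1.4249e-4,2.2525e-4,2.2525e-4,0.002062,165000,synthetic
24,1.5899e-4,2.3732e-4,2.3732e-4,0.002276,165000,synthetic
25,1.7738e-4,2.5056e-4,2.5056e-4,0.002512,165000,synthetic
26,1.9785e-4,2.6507e-4,2.6507e-4,0.002771,165000,synthetic
27,2.2063e-4,2.8097e-4,2.8097e-4,0.003058,165000,synthetic
28,2.4598e-4,2.9841e-4,2.9841e-4,0.003373,165000,synthetic
29,2.7417e-4,3.1753e-4,3.1753e-4,0.0037200000000000002,165000,synthetic
30,3.0549e-4,3.3849e-4,3.3849e-4,0.004102,165000,synthetic
31,3.4028e-4,3.6148e-4,3.6148e-4,0.004521,165000,synthetic
32,3.789e-4,3.8667e-4,3.8667e-4,0.004983,165000,synthetic
33,4.2172e-4,4.143e-4,4.143e-4,0.00549,165000,synthetic
34,4.6916e-4,4.4459e-4,4.4459e-4,0.006047,165000,synthetic
35,5.2168e-4,4.7779e-4,4.7779e-4,0.006658,165000,synthetic
36,5.7976e-4,5.142e-4,5.142e-4,0.007328,165000,synthetic
37,6.4391e-4,5.5411e-4,5.5411e-4,0.008062,165000,synthetic
38,7.1466e-4,5.9787e-4,5.9787e-4,0.008866,165000,synthetic
39,7.926e-4,6.4585e-4,6.4585e-4,0.009745,165000,synthetic
40,8.783e-4,6.9845e-4,0.00125721,0.010705,165000,synthetic
41,9.724e-4,7.5612e-4,0.00136102,0.011754,165000,synthetic
42,0.0010755,8.1935e-4,0.00147483,0.012896,165000,synthetic
43,0.00118824,8.8867e-4,0.0015996,0.014139,165000,synthetic
44,0.00131123,9.6467e-4,0.0017364,0.015491,165000,synthetic
45,0.00144508,0.00104799,0.00188638,0.016958,165000,synthetic
46,0.00159036,0.00113934,0.00205082,0.018546,165000,synthetic
47,0.00174756,0.0012395,0.0022311,0.020264,165000,synthetic
48,0.00191714,0.00134931,0.00242875,0.022118,165000,synthetic
49,0.00209944,0.0014697,0.00264545,0.024115,165000,synthetic
50,0.00229469,0.00160169,0.00288304,0.026259,165000,synthetic
51,0.002503,0.0017464,0.00314351,0.028557,162000,synthetic
52,0.0027243,0.00190505,0.00342909,0.031012,159000,synthetic
53,0.00295836,0.002079,0.00374219,0.033629,156000,synthetic
54,0.00320473,0.0022697,0.00408546,0.036408,153000,synthetic
55,0.00346279,0.00247878,0.00446181,0.039351,150000,synthetic
56,0.00373168,0.00270801,0.00487443,0.042456,147000,synthetic
57,0.00401034,0.00295934,0.0053268,0.04572,144000,synthetic
58,0.00429751,0.00323487,0.00582277,0.049139,141000,synthetic
59,0.00459173,0.00353697,0.00636654,0.052704,138000,synthetic
60,0.00489139,0.00386817,0.0069627,0.056408,135000,synthetic
61,0.00519476,0.00423129,0.00761632,0.060238,132000,synthetic
62,0.0055,0.0046294,0.00833292,0.064182,129000,synthetic
63,0.00580524,0.00506587,0.00911857,0.068223,126000,synthetic
64,0.00610861,0.00554441,0.00997994,0.072345,123000,synthetic
65,0.00640827,0.00606906,0.01092431,0.076528,120000,synthetic
66,0.00670249,0.00664427,0.01195968,0.080754,117000,synthetic
67,0.00698966,0.0072749,0.01309483,0.085,114000,synthetic
68,0.00726832,0.00796631,0.01433936,0.089246,111000,synthetic
69,0.00753721,0.00872435,0.01570383,0.093472,108000,synthetic
70,0.00779527,0.00955543,0.01719978,0.097655,105000,synthetic
71,0.00804164,0.0104666,0.01883988,0.101777,102000,synthetic
72,0.0082757,0.01146558,0.02063804,0.105818,99000,synthetic
73,0.008497,0.01256082,0.02260948,0.109762,96000,synthetic
74,0.00870531,0.0137616,0.02477089,0.113592,93000,synthetic
75,0.00890056,0.0150781,0.02714058,0.117296,90000,synthetic
76,0.00908286,0.01652146,0.02973864,0.120861,87000,synthetic
77,0.00925244,0.01810392,0.03258705,0.12428,84000,synthetic
78,0.00940964,0.01983886,0.03570995,0.127544,81000,synthetic
79,0.00955492,0.02174099,0.03913379,0.130649,78000,synthetic
80,0.00968877,0.02382642,0.04288756,0.133592,75000,synthetic
81,0.00981176,0.02611281,0.04700307,0.136371,72000,synthetic
82,0.0099245,0.02861953,0.05151516,0.138988,69000,synthetic
83,0.0100276,0.03136781,0.05646207,0.141443,66000,synthetic
84,0.0101217,0.03438093,0.06188568,0.143741,63000,synthetic
85,0.0102074,0.03768441,0.06783193,0.145885,60000,synthetic
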