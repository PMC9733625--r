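age,q_male,q_female
40,0.001722,0.000999
41,0.001821,0.001057
42,0.001931,0.001121
43,0.002053,0.001193
44,0.002188,0.001273
45,0.002338,0.001362
46,0.002503,0.001461
47,0.002687,0.001572
48,0.002891,0.001695
49,0.003116,0.001833
50,0.003366,0.001987
51,0.003642,0.002158
52,0.003949,0.002349
53,0.004288,0.002563
54,0.004664,0.0028
55,0.005081,0.003065
56,0.005542,0.003361
57,0.006054,0.003691
58,0.00662,0.004059
59,0.007248,0.004469
60,0.007943,0.004927
61,0.008713,0.005437
62,0.009566,0.006006
63,0.010511,0.006641
64,0.011558,0.007349
65,0.012718,0.008138
66,0.014003,0.009019
67,0.015427,0.01
68,0.017004,0.011096
69,0.018751,0.012317
70,0.020686,0.013679
71,0.02283,0.015198
72,0.025205,0.016893
73,0.027836,0.018782
74,0.030751,0.02089
75,0.03398,0.02324
76,0.037558,0.025862
77,0.041521,0.028785
78,0.045911,0.032046
79,0.050775,0.035682
80,0.056163,0.039738
81,0.062132,0.044261
82,0.068744,0.049306
83,0.07607,0.054932
84,0.084185,0.061206
85,0.093175,0.068204
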