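age,qx
75,0.018
76,0.019794
77,0.021766
78,0.023936
79,0.026321
80,0.028944
81,0.031829
82,0.035001
83,0.038489
84,0.042325
85,0.046543
86,0.051181
87,0.056282
88,0.061891
89,0.068059
90,0.074841
91,0.0823
92,0.090502
93,0.099521
94,0.109439
95,0.120346
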