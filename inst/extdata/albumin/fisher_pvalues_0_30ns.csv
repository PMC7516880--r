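replica,300K,303K,306K,309K,312K
1,0.439,0.737,0.367,0.754,0.643
2,0.153,0.660,0.961,0.922,0.835
3,0.320,0.483,0.012,0.558,0.0551
4,0.263,0.372,0.700,0.223,0.323
5,0.544,0.657,0.057,0.130,0.066
6,0.114,0.385,0.232,0.416,0.360
7,0.499,0.529,0.008,0.006,0.007
8,0.013,0.871,0.610,0.692,0.456
9,0.245,0.891,0.871,0.832,0.694
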