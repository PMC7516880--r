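replica,300K,303K,306K,309K,312K
1,0.328,0.720,0.460,0.078,0.041
2,0.183,0.890,0.146,0.713,0.898
3,0.092,0.378,0.219,0.464,0.264
4,0.764,0.800,0.440,0.629,0.297
5,0.030,0.802,0.275,0.323,0.313
6,0.220,0.108,0.330,0.440,0.540
7,0.279,0.121,0.382,0.253,0.046
8,0.582,0.299,0.976,0.324,0.457
9,0.438,0.550,0.438,0.951,0.642
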