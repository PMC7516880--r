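window,temperature,r_rms
0-30ns,300K,47.88
0-30ns,303K,46.69
0-30ns,306K,46.72
0-30ns,309K,47.09
0-30ns,312K,47.81
70-100ns,300K,47.12
70-100ns,303K,46.67
70-100ns,306K,47.72
70-100ns,309K,47.13
70-100ns,312K,47.64
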