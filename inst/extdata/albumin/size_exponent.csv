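window,temperature,mu
0-30ns,300K,0.3986
0-30ns,303K,0.3947
0-30ns,306K,0.3948
0-30ns,309K,0.3960
0-30ns,312K,0.3984
70-100ns,300K,0.3961
70-100ns,303K,0.3946
70-100ns,306K,0.3981
70-100ns,309K,0.3961
70-100ns,312K,0.3978
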