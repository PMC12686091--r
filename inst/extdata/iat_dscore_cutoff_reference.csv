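cutoff,label,lower,upper
0,no_bias,-0.38,0.38
0.15,weak,-0.21,0.51
0.35,moderate,0.02,0.68
0.65,strong,0.36,0.94
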