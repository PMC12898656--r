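variable,n_a,mean_a,sd_a,n_b,mean_b,sd_b
age,31,50.71,9.795,34,48.35,9.39
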