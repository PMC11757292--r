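p_cnn,p_periodontist,k0,deviation_percent,k1,n
0.734,0.766,0.766,25,0.9575,83
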