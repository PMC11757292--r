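rater,0,1,2,3,4
0,0,0,0,0,0
1,0,1,0,0,0
2,4,0,29,6,0
3,1,4,6,35,1
4,0,0,1,2,0
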