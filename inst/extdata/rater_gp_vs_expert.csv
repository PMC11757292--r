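rater,0,1,2,3,4
0,5,4,8,0,0
1,0,1,14,3,0
2,0,0,11,15,0
3,0,0,3,22,0
4,0,0,0,3,1
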