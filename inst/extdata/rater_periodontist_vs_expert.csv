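rater,0,1,2,3,4
0,5,1,6,1,0
1,0,4,8,0,0
2,0,0,20,8,0
3,0,0,2,34,0
4,0,0,0,0,1
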