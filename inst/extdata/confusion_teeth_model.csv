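model,tp,fp,fn,tn
teeth_segmentation,983,589,11,18687
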