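target,level,start,end
EGFR,-1,10,
TNFR,0.8,20,
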