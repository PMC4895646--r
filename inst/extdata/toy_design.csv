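condition,node,level
control,EGFR,0.5
control,TNFR,0.5
control,DNADamage,random
egfr_inhibitor,EGFR,-1
egfr_inhibitor,TNFR,0.5
egfr_inhibitor,DNADamage,random
dna_damage,EGFR,random
dna_damage,TNFR,0.5
dna_damage,DNADamage,1
both_drugs,EGFR,-1
both_drugs,TNFR,0.5
both_drugs,DNADamage,1
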