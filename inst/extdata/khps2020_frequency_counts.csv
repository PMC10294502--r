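disease,AG_consequent,AG_antecedent,AG_total,IG_consequent,IG_antecedent,IG_total
spondylosis,5,2,7,8,9,17
gonarthrosis,7,3,10,9,12,21
hypertension,7,7,14,13,15,28
diabetes,4,4,8,7,11,18
arthritis,0,2,2,0,4,4
cardiovascular_disease,0,4,4,0,10,10
cerebrovascular_disease,0,1,1,0,1,1
obesity,0,3,3,0,4,4
depression,0,0,0,0,1,1
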