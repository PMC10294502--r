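consequent,antecedent,confidence_pct,support_pct,lift,exclusive
diabetes,cardiovascular_disease,32.99,2.04,1.83,0
diabetes,gonarthrosis;hypertension,30.68,2.78,1.70,0
diabetes,hypertension;obesity,38.22,1.55,2.12,0
diabetes,hypertension;spondylosis,28.71,2.59,1.59,0
hypertension,cardiovascular_disease,61.86,3.82,1.56,0
hypertension,cerebrovascular_disease,69.00,2.93,1.74,0
hypertension,diabetes,63.13,11.37,1.59,0
hypertension,diabetes;spondylosis,69.71,2.59,1.75,0
hypertension,diabetes;gonarthrosis,71.58,2.78,1.80,0
hypertension,diabetes;obesity,87.95,1.55,2.21,0
hypertension,gonarthrosis;obesity,71.72,1.51,1.80,0
gonarthrosis,arthritis,34.20,2.23,2.11,0
gonarthrosis,cardiovascular_disease,27.15,1.68,1.67,0
gonarthrosis,diabetes;hypertension,24.44,2.78,1.51,0
gonarthrosis,diabetes;spondylosis,42.29,1.57,2.61,0
gonarthrosis,obesity,30.84,2.10,1.90,1
gonarthrosis,hypertension;obesity,37.17,1.51,2.29,0
gonarthrosis,hypertension;spondylosis,41.65,3.75,2.57,0
spondylosis,arthritis,34.20,2.23,1.91,0
spondylosis,cardiovascular_disease,28.52,1.76,1.59,0
spondylosis,gonarthrosis,39.22,6.36,2.19,0
spondylosis,diabetes;gonarthrosis,40.44,1.57,2.26,0
spondylosis,gonarthrosis;hypertension,41.45,3.75,2.31,0
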