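consequent,antecedent,confidence_pct,support_pct,lift,exclusive
diabetes,cardiovascular_disease,35.51,2.31,2.06,0
diabetes,cardiovascular_disease;hypertension,40.12,1.73,2.33,1
diabetes,gonarthrosis;hypertension,31.60,3.72,1.84,0
diabetes,hypertension;obesity,34.60,1.94,2.01,0
diabetes,hypertension;spondylosis,31.52,3.24,1.83,0
diabetes,gonarthrosis;hypertension;spondylosis,36.51,1.83,2.12,1
diabetes,gonarthrosis;spondylosis,28.30,2.34,1.64,0
hypertension,cardiovascular_disease,66.12,4.31,1.62,0
hypertension,cardiovascular_disease;diabetes,74.71,1.73,1.84,1
hypertension,cardiovascular_disease;gonarthrosis,78.67,1.57,1.93,1
hypertension,cardiovascular_disease;spondylosis,72.15,1.52,1.77,1
hypertension,cerebrovascular_disease,69.09,3.03,1.70,0
hypertension,depression,63.39,1.89,1.56,1
hypertension,diabetes,68.78,11.83,1.69,0
hypertension,diabetes;gonarthrosis,79.10,3.72,1.94,0
hypertension,diabetes;gonarthrosis;spondylosis,78.41,1.83,1.93,1
hypertension,diabetes;spondylosis,71.76,3.24,1.76,0
hypertension,gonarthrosis,62.13,11.78,1.53,1
hypertension,diabetes;obesity,78.49,1.94,1.93,0
hypertension,gonarthrosis;obesity,72.16,1.86,1.77,0
gonarthrosis,arthritis,38.46,3.19,2.03,0
gonarthrosis,arthritis;hypertension,42.50,1.81,2.24,1
gonarthrosis,cardiovascular_disease,30.61,1.99,1.61,0
gonarthrosis,cardiovascular_disease;hypertension,36.42,1.57,1.92,1
gonarthrosis,diabetes;hypertension,31.46,3.72,1.66,0
gonarthrosis,diabetes;spondylosis,51.76,2.34,2.73,0
gonarthrosis,diabetes;hypertension;spondylosis,56.56,1.83,2.98,1
gonarthrosis,hypertension;obesity,33.18,1.86,1.75,0
gonarthrosis,hypertension;spondylosis,48.84,5.03,2.58,0
spondylosis,arthritis,33.97,2.82,1.72,0
spondylosis,arthritis;hypertension,36.25,1.54,1.84,1
spondylosis,cardiovascular_disease,32.24,2.10,1.64,0
spondylosis,cardiovascular_disease;hypertension,35.19,1.52,1.79,1
spondylosis,diabetes;gonarthrosis;hypertension,49.29,1.83,2.50,1
spondylosis,diabetes;gonarthrosis,49.72,2.34,2.52,0
spondylosis,gonarthrosis,43.62,8.27,2.21,0
spondylosis,gonarthrosis;hypertension,42.66,5.03,2.17,0
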