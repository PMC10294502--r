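variable,category,n,mcd_n
sex,male,3727,1268
sex,female,4750,2049
age_band,46-55,1839,234
age_band,56-65,2515,675
age_band,66-75,2474,1329
age_band,>75,1649,1079
education,elementary_or_below,2517,1577
education,middle,1549,700
education,high,2778,754
education,university_or_above,1623,286
exercise,yes,4716,1774
exercise,no,3761,1543
total,total,8477,3317
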