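strain,source_cu_mg_l,pct_inhibition_0.01,pct_inhibition_0.1
Chlorella kesslerii CPCC266,NA,0,0
Sp21.20,0.0021,5.25,5.84
Sp11.30,0.0035,0,0
Sp14.35,0.0061,0,1.04
Sp17.38,0.0040,0,0.22
Sp21.01,0.0021,0.86,53.4
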