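condition,nominal_ng_ml,mean_ng_ml,sd_ng_ml,rsd_pct,e_pct
long_term,3,2.95,0.07,2.20,-1.56
long_term,2400,2356.31,10.59,0.45,-1.82
short_term,3,3.10,0.03,0.85,3.33
short_term,2400,2393.57,15.31,0.64,-0.27
autosampler,3,3.12,0.02,0.67,3.78
autosampler,2400,2368.44,12.85,0.54,-1.31
freeze_thaw,3,3.09,0.04,1.31,3.22
freeze_thaw,2400,2370.79,8.10,0.34,-1.22
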