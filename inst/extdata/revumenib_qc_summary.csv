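timeframe,nominal_ng_ml,mean_ng_ml,sd_ng_ml,rsd_pct,e_pct,recovery_pct
intra_day,1,1.11,0.02,1.87,11.33,111.33
intra_day,3,3.22,0.04,1.35,7.33,107.33
intra_day,900,916.03,8.26,0.90,1.78,101.78
intra_day,2400,2394.47,8.65,0.36,-0.23,99.77
inter_day,1,1.12,0.03,2.88,11.67,111.67
inter_day,3,3.16,0.06,1.98,5.33,105.33
inter_day,900,918.18,9.69,1.06,2.02,102.02
inter_day,2400,2378.88,12.26,0.52,-0.88,99.12
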