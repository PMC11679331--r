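nominal_ng_ml,mean_ng_ml,sd_ng_ml,rsd_pct,e_pct,recovery_pct
1,1.11,0.02,1.87,11.33,111.33
15,16.23,0.39,2.39,8.18,108.18
50,52.96,1.60,3.01,5.91,105.91
150,152.99,4.54,2.96,2.00,102.00
300,292.86,4.34,1.48,-2.38,97.62
400,415.41,8.60,2.07,3.85,103.85
500,489.94,3.70,0.76,-2.01,97.99
1500,1530.01,20.80,1.36,2.00,102.00
3000,3086.33,32.63,1.06,2.88,102.88
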