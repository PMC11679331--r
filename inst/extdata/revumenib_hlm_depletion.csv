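time_min,replicate,conc_ng_ml,analyte,nadph
0,1,618.73,revumenib,plus
2.5,1,572.18,revumenib,plus
5,1,524.64,revumenib,plus
7.5,1,475.34,revumenib,plus
15,1,357.19,revumenib,plus
20,1,243.18,revumenib,plus
30,1,158.91,revumenib,plus
40,1,152.13,revumenib,plus
50,1,145.85,revumenib,plus
60,1,142.76,revumenib,plus
70,1,135.79,revumenib,plus
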