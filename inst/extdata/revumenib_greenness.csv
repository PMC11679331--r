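criterion_index,score,weight,note
1,0.3,2,direct analysis not possible; protein precipitation required
2,1.0,2,minimal sample size
3,0.66,2,off-line measurement
4,1.0,2,integrated procedure saves energy and reagents
5,0.75,2,partially automated
6,1.0,2,no derivatization
7,0.69,2,moderate waste volume
8,1.0,2,multi-analyte run
9,0.0,2,MS/MS is energy intensive
10,1.0,2,reagents from sustainable sources
11,1.0,2,no hazardous chemicals
12,0.8,2,operator safety
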