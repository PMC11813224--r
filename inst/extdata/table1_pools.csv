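variant,species,value_nM,status
WT-L,Ab49,56.0,OK
WT-L,Ab46,201.7,OK
WT-L,Ab43,103.3,OK
WT-L,Ab40,196.9,OK
WT-L,Ab48,131.5,OK
WT-L,Ab45,153.3,OK
WT-L,Ab42,231.6,OK
WT-L,Ab38,34.2,OK
WT-H,Ab49,26.3,OK
WT-H,Ab46,176.3,OK
WT-H,Ab43,121.0,OK
WT-H,Ab40,191.8,OK
WT-H,Ab48,91.2,OK
WT-H,Ab45,180.9,OK
WT-H,Ab42,232.0,OK
WT-H,Ab38,23.7,OK
S169L,Ab49,3.7,OK
S169L,Ab46,52.7,OK
S169L,Ab43,-2.8,OK
S169L,Ab40,42.5,OK
S169L,Ab48,264.6,OK
S169L,Ab45,52.8,OK
S169L,Ab42,53.8,OK
S169L,Ab38,12.9,OK
S170F,Ab49,38.4,OK
S170F,Ab46,128.3,OK
S170F,Ab43,-2.8,OK
S170F,Ab40,67.9,OK
S170F,Ab48,-173.5,OK
S170F,Ab45,221.2,OK
S170F,Ab42,80.8,OK
S170F,Ab38,4.9,OK
G378E,Ab49,44.2,OK
G378E,Ab46,76.7,OK
G378E,Ab43,-5.5,OK
G378E,Ab40,21.6,OK
G378E,Ab48,112.2,OK
G378E,Ab45,88.9,OK
G378E,Ab42,19.2,OK
G378E,Ab38,1.3,OK
F386S,Ab49,41.4,OK
F386S,Ab46,222.9,OK
F386S,Ab43,140.9,OK
F386S,Ab40,41.2,OK
F386S,Ab48,634.8,OK
F386S,Ab45,180.1,OK
F386S,Ab42,43.3,OK
F386S,Ab38,4.3,OK
A431E,Ab49,NA,ND
A431E,Ab46,8.3,OK
A431E,Ab43,-8.8,OK
A431E,Ab40,8.8,OK
A431E,Ab48,NA,ND
A431E,Ab45,52.6,OK
A431E,Ab42,5.1,OK
A431E,Ab38,0.4,OK
A434T,Ab49,NA,ND
A434T,Ab46,0,OK
A434T,Ab43,-7.9,OK
A434T,Ab40,7.9,OK
A434T,Ab48,NA,ND
A434T,Ab45,9.2,OK
A434T,Ab42,9.4,OK
A434T,Ab38,0.3,OK
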