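treatment,band,stage,reflectance_pct
W,Red,HS,7.68
W,Red,FL,7.65
W,Red,GF,5.85
W,RedEdge,HS,34.03
W,RedEdge,FL,33.11
W,RedEdge,GF,27.22
W,Nir,HS,56.84
W,Nir,FL,55.14
W,Nir,GF,37.47
W,Green,HS,15.93
W,Green,FL,15.06
W,Green,GF,7.7
W,Blue,HS,6.74
W,Blue,FL,6.38
W,Blue,GF,4.54
D,Red,HS,7.88
D,Red,FL,7.7
D,Red,GF,6.95
D,RedEdge,HS,33.74
D,RedEdge,FL,31.42
D,RedEdge,GF,27.88
D,Nir,HS,55.4
D,Nir,FL,52.33
D,Nir,GF,34.93
D,Green,HS,15.82
D,Green,FL,14.81
D,Green,GF,8.31
D,Blue,HS,6.7
D,Blue,FL,6.38
D,Blue,GF,4.94
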