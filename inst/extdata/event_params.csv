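size_min,size_max,X,F,G
1,1,1.00,0.0,0.0
2,2,0.83,0.8,1.0
3,3,0.72,0.8,5.2
4,4,0.59,0.4,3.71
5,5,0.51,0.6,1.28
6,10,0.23,0.75,0.42
11,15,0.2,0.67,0.36
16,Inf,0.18,0.6,0.33
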