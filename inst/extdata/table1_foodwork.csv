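category,median,q1,q3,geometric_mean
none,0,0,0,0
some,30,20,50,28.5
more,110,90,150,116.2
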