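category,n,mean,sd
none,1455,41.8,18.7
some,2454,46.8,17.6
more,2234,53.2,17.3
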