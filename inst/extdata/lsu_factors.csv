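species,region,factor
buffalo,1,0.7
cattle,1,0.7
goats,1,0.1
horses,1,0.8
sheep,1,0.1
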