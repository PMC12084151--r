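veg_class,pft_low_lat,pft_high_lat
tree,5,7
shrub,10,10
grass,13,13
crop,15,15
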