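class,pft,weight
evergreen_needleleaf_forest,1,1
evergreen_broadleaf_forest,5,1
deciduous_needleleaf_forest,3,1
deciduous_broadleaf_forest,7,1
mixed_forest,1,0.5
mixed_forest,7,0.5
shrubland,10,1
grassland,13,1
cropland,15,1
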