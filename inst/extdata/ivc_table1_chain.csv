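code,name,level,parent_code
1,Grassland & Shrubland,1,
201,Temperate & Boreal Grassland & Shrubland,2,1
301,Temperate Grassland & Shrubland,3,201
401,Great Plains Grassland & Shrubland,4,301
5001,Great Plains Tallgrass Prairie,5,401
6001,Northern Great Plains Tallgrass Prairie,6,5001
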