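product,code,composite
globcover_like,11,AGRICULTURE
globcover_like,14,AGRICULTURE
globcover_like,20,AGRICULTURE
globcover_like,30,AGRICULTURE
globcover_like,40,NONE
globcover_like,50,NONE
globcover_like,60,NONE
globcover_like,70,NONE
globcover_like,90,NONE
globcover_like,100,NONE
globcover_like,110,NONE
globcover_like,120,NONE
globcover_like,130,NONE
globcover_like,140,NONE
globcover_like,150,NONE
globcover_like,160,NONE
globcover_like,170,NONE
globcover_like,180,NONE
globcover_like,190,DEVELOPED
globcover_like,200,NONE
globcover_like,210,WATER
globcover_like,220,NONE
globeland30_like,10,AGRICULTURE
globeland30_like,20,NONE
globeland30_like,30,NONE
globeland30_like,40,NONE
globeland30_like,50,NONE
globeland30_like,60,WATER
globeland30_like,70,NONE
globeland30_like,80,DEVELOPED
globeland30_like,90,NONE
globeland30_like,100,NONE
landfire_like,1,NONE
landfire_like,2,DEVELOPED
landfire_like,3,AGRICULTURE
landfire_like,4,RUDERAL
landfire_like,5,WATER
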