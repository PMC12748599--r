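map,NoChange,Wildfire,Harvesting,Windthrow,Pest_Harv,Pest
NoChange,531,8,31,9,2,95
Wildfire,0,116,0,0,0,2
Harvesting,3,0,96,3,6,3
Windthrow,1,3,4,10,0,6
Pest_Harv,0,2,3,0,18,0
Pest,7,10,5,0,1,96
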