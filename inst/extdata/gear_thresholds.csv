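subarea,gear,threshold_kg
FC,Campelen 1800 & Lofoten,70
NL,Campelen 1800,200
HS,Cosmos,40
HS,Alfredo,70
HS,Campelen 1800,40
BB,Cosmos,40
BB,Alfredo,70
BB,Campelen 1800,40
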