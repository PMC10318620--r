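species,distance_group,tag_type,offshore,onshore,departed_unrouted,not_detected,tagged
Dunnock,short,NTQB,7,8,1,17,33
Eurasian Blackbird,short,ACT,9,6,10,10,35
Song Thrush,short,ACT,3,6,8,12,29
Redwing,short,ACT,0,3,8,8,19
Blackcap,short,NTQB,11,23,15,33,82
Garden Warbler,long,NTQB,7,27,4,13,51
Northern Wheatear,long,NTQB,12,4,12,12,40
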