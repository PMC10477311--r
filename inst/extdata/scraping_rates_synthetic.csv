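species,size_class,bite_rate,bite_area
Scarus niger,10-20,28,45
Scarus niger,20-30,20,110
Scarus niger,30-40,14,210
Scarus frenatus,10-20,26,50
Scarus frenatus,20-30,19,120
Scarus frenatus,30-40,13,230
Scarus psittacus,10-20,30,35
Scarus psittacus,20-30,22,90
Scarus rivulatus,10-20,27,48
Scarus rivulatus,20-30,20,115
Chlorurus sordidus,10-20,24,55
Chlorurus sordidus,20-30,17,140
Chlorurus sordidus,30-40,12,260
Chlorurus microrhinos,20-30,14,200
Chlorurus microrhinos,30-40,10,420
Chlorurus microrhinos,40+,7,780
Hipposcarus longiceps,20-30,15,130
Hipposcarus longiceps,30-40,11,240
Bolbometopon muricatum,40+,4,1500
Cetoscarus ocellatus,30-40,10,300
Cetoscarus ocellatus,40+,7,550
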