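id,habitat,length_km,n_nests,esw_m
LF1,logged_forest,1.8,31,15.5
LF2,logged_forest,2,23,15.5
LF3,logged_forest,2,25,15.5
LFR,logged_forest,1,15,15.5
LFE1,logged_forest,2,17,15.5
LFE2,logged_forest,1.5,24,15.5
LFE3,logged_forest,1.2,24,15.5
LFE4,logged_forest,1,17,15.5
LFER,logged_forest,1.6,25,15.5
VJR_R,logged_forest,1.6,25,15.5
VJR_1,logged_forest,1.2,37,15.5
VJR_2,logged_forest,1,10,15.5
RR0,salvage_logged,1.6,30,14.3
RR5,salvage_logged,1.5,26,14.3
RR15,salvage_logged,1.6,28,14.3
RR30,salvage_logged,1.7,29,14.3
RR60,salvage_logged,1.5,11,14.3
RR120,salvage_logged,1.6,21,14.3
Block_B,salvage_logged,1.9,28,14.3
Block_C,salvage_logged,2.1,29,14.3
Block_D,salvage_logged,2.4,24,14.3
Block_E,salvage_logged,2.3,43,14.3
OP02,oil_palm_remnant,1.6,13,14.7
OP03,oil_palm_remnant,1.3,9,14.7
OP07,oil_palm_remnant,1.8,1,14.7
OP12,oil_palm_remnant,1.8,6,14.7
OP14,oil_palm_remnant,1.8,16,14.7
OP16,oil_palm_remnant,1.8,7,14.7
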