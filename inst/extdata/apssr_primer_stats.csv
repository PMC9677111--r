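primer,TNB,NPB,PP,PIC,RP,EMR,MI,QM,QND,EMI
APSSR1,2,2,100,0.326,1.833,2,0.653,1,0.75,0.490
APSSR3,2,2,100,0.345,1.750,2,0.691,1,0.75,0.518
APSSR5,2,2,100,0.283,1.583,2,0.566,1,0.75,0.424
APSSR6,2,2,100,0.450,1.750,2,0.899,1,0.75,0.674
APSSR7,2,2,100,0.149,1.833,2,0.299,1,0.75,0.224
APSSR12,2,2,100,0.465,1.500,2,0.931,1,0.75,0.698
APSSR14,2,2,100,0.299,1.500,2,0.597,1,0.75,0.448
APSSR16,2,2,100,0.352,2.917,2,0.705,1,0.75,0.529
APSSR17,2,2,100,0.387,1.417,2,0.774,1,0.75,0.581
APSSR18,2,2,100,0.247,1.500,2,0.493,1,0.75,0.370
APSSR19,2,2,100,0.247,0.667,2,0.493,1,0.75,0.370
APSSR29,2,2,100,0.274,1.833,2,0.549,1,0.75,0.411
APSSR33,2,2,100,0.361,1.667,2,0.722,1,0.75,0.542
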