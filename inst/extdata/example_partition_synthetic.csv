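region_label,subnetwork_label
R1,BGN
R2,BGN
R3,BGN
R4,BGN
R5,CEREN
R6,CEREN
R7,CEREN
R8,CEREN
R9,DAN
R10,DAN
R11,DAN
R12,DAN
R13,DMN
R14,DMN
R15,DMN
R16,DMN
R17,FPN
R18,FPN
R19,FPN
R20,FPN
R21,LN
R22,LN
R23,LN
R24,LN
R25,SMN
R26,SMN
R27,SMN
R28,SMN
R29,VAN
R30,VAN
R31,VAN
R32,VAN
R33,VN
R34,VN
R35,VN
R36,VN
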