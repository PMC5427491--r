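line,M01,M02,M03,M04,M05,M06,M07,M08,M09,M10,M11,M12,M13,M14,M15,M16,M17,M18,M19,M20,M21,M22,M23,M24,M25,M26,M27,M28,M29,M30
L001,0,1,1,0,1,1,1,0,0,1,1,1,1,1,1,0,NA,0,0,0,1,NA,1,0,0,0,1,NA,0,0
L002,0,0,1,0,0,1,0,1,1,1,1,0,1,1,1,1,0,1,0,0,1,0,1,NA,1,1,1,1,0,0
L003,0,1,0,0,0,1,0,0,1,0,0,1,1,0,0,1,NA,0,1,0,0,0,1,0,1,0,1,0,1,1
L004,0,1,1,0,1,0,0,0,0,NA,1,0,1,0,1,0,1,0,0,1,0,1,1,0,NA,1,1,0,1,0
L005,0,1,0,0,1,0,1,0,1,1,1,0,0,0,0,1,0,0,0,1,0,0,0,1,0,0,0,0,0,0
L006,0,0,1,1,1,0,1,0,0,1,0,0,1,0,1,0,1,1,0,0,0,1,0,1,NA,1,0,1,1,0
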