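SLC2A4
FOXO3
PPP2CB
PIK3CD
CAB39L
CCNA1
FBP1
FBP2
FOXO1
HMGCR
IRS2
PIK3R1
SIRT1
TBC1D1
PPARGC1A
PPP2R2C
MLYCD
PFKFB3
PPP2R2B
PRKAA2
LEPR
CAB39
IRS1
PFKFB1
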