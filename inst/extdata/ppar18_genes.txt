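PLIN5
PPARG
ACADM
GK
CPT2
SCP2
ACAA1
APOA1
PPARA
ACOX2
ANGPTL4
FABP3
PLIN2
AQP7
ACSL1
FABP5
ACADL
PCK2
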