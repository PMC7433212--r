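gene	sign
AKT1	1
MTOR	1
GSK3B	1
RPS6KB1	1
RPS6	1
PTEN	-1
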