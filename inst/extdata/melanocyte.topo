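Source Target Type
MITF LEF1 1
LEF1 MITF 1
MITF MYC 2
MYC MITF 2
MYC E2F 1
RB E2F 2
MYC CycD 1
CycD RB 2
E2F CycE 1
CycE RB 2
E2F E2F 1
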