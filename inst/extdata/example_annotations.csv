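ligand_id,class_label
ESR_001,ESR
ESR_002,ESR
ESR_003,ESR
ESR_004,ESR
ESR_005,ESR
ESR_006,ESR
ESR_007,ESR
ESR_008,ESR
VDR_001,VDR
VDR_002,VDR
VDR_003,VDR
VDR_004,VDR
VDR_005,VDR
VDR_006,VDR
VDR_007,VDR
VDR_008,VDR
CTSD_001,CTSD
CTSD_002,CTSD
CTSD_003,CTSD
CTSD_004,CTSD
CTSD_005,CTSD
CTSD_006,CTSD
CTSD_007,CTSD
CTSD_008,CTSD
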