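compound,shift_cm1
PS,1001
PS,1031
PS,1602
PS,2904
PS,3054
PMMA,812
PMMA,1450
PMMA,1730
PMMA,2950
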