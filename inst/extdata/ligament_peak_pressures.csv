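label,P1,P2
Reference configuration,2.93,6.22
MCL+LCL AP 5 mm,2.84,5.22
MCL anterior 5 mm,2.74,5.14
MCL posterior 5 mm,2.93,6.34
LCL anterior 5 mm,2.91,6.44
LCL posterior 5 mm,2.93,6.08
MCL+LCL ML 5 mm,2.93,6.33
MCL medial 5 mm,2.93,6.89
MCL lateral 5 mm,2.93,6.33
LCL medial 5 mm,2.93,6.08
LCL lateral 5 mm,2.93,6.08
MCL+LCL PD 5 mm,2.93,6.68
MCL proximal 5 mm,2.93,7.06
MCL distal 5 mm,2.92,5.69
LCL proximal 5 mm,2.93,6.08
LCL distal 5 mm,2.93,6.08
MCL+LCL eps_r -5%,2.93,6.28
MCL eps_r -5%,2.93,6.26
LCL eps_r -5%,2.93,6.08
MCL+LCL eps_r +5%,2.82,5.71
MCL eps_r +5%,2.93,6.11
LCL eps_r +5%,2.93,6.08
MCL+LCL eps_r -10%,2.93,6.28
MCL eps_r -10%,2.93,6.35
LCL eps_r -10%,2.93,6.08
MCL+LCL eps_r +10%,2.93,6.27
MCL eps_r +10%,2.93,6.71
LCL eps_r +10%,2.93,6.08
MCL+LCL k -10%,2.93,6.28
MCL k -10%,2.93,6.21
LCL k -10%,2.93,6.08
MCL+LCL k +10%,2.93,6.21
MCL k +10%,2.93,6.21
LCL k +10%,2.93,6.08
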