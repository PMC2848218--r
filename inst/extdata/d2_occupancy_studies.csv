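study_label,cohort,occupancy_percent
Abi-Dargham 2000,HC,12
Abi-Dargham 2000,SZ,21
Erlandsson 2003,HC,45
Laruelle 1997,HC,26
Riccardi 2008,HC,13
Verhoeff 2001,HC,22
Voruganti 2001,SZ,16
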