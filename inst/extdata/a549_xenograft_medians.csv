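group,day,median_volume_mm3
vehicle (control),14,154
PRI-2191 s.c.,14,98
PRI-2191 oral,14,92
GV,14,134
GV + PRI-2191 s.c.,14,76
GV + PRI-2191 oral,14,96
vehicle (control),21,460
PRI-2191 s.c.,21,305
PRI-2191 oral,21,263
GV,21,486
GV + PRI-2191 s.c.,21,262
GV + PRI-2191 oral,21,287
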