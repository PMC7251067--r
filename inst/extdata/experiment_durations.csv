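animal_id,hours
PV-Cre 1,7.5
PV-Cre 2,5.25
PV-Cre 3,5.25
VGat-Cre 1,6
VGat-Cre 2,4.5
VGat-Cre 3,3.75
VGlut-Cre 1,5.25
VGlut-Cre 2,5.25
VGlut-Cre 3,3.75
ChAT-Cre 1,4.5
ChAT-Cre 2,3.75
ChAT-Cre 3,3.75
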