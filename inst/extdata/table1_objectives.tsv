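ID	formula	description
Glu2Gln	1 glu_L[e] -> 1 gln_L[e]	Glutamate - Glutamine cycle
Gly2SerD	1 gly[e] -> 1 ser_D[e]	Glycine to D-serine conversion
Glc2Lac	1 glc_D[e] -> 2 lac_L[e]	Lactate production from glucose
Glc2ATP	1 glc_D[e] -> 36 atp[e]	ATP production from glucose
Cys2GTHRD	1 cys_L[e] + 1 glu_L[c] + 1 gly[c] -> 1 gthrd[e]	Catch of cysteine to produce reduced glutathione
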