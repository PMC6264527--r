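line	temperature	n_hom	n_het
XLOC_004366_a	25	22	47
XLOC_004366_a	29	16	34
XLOC_004366_b	25	30	61
XLOC_004366_b	29	25	45
XLOC_012225_a	25	22	40
XLOC_012225_a	29	17	36
XLOC_012225_b	25	36	65
XLOC_012225_b	29	23	50
XLOC_012319	25	22	42
XLOC_012319	29	16	34
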