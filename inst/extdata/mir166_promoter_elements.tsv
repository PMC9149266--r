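promoter	gibberellin	methyl_jasmonate	salicylic_acid	auxin	abscisic_acid	defense_stress	drought	low_temperature	anaerobic
miR166a	1	0	1	0	0	0	1	1	1
miR166b	1	1	0	1	1	0	0	0	1
miR166c	0	0	0	1	1	0	0	0	1
miR166d	1	0	0	1	1	1	1	0	1
miR166e	1	1	0	1	1	0	0	0	1
miR166f	1	1	0	0	1	0	1	0	1
miR166g	1	1	0	1	1	0	0	1	1
miR166h	0	1	1	1	1	0	1	1	1
miR166i	1	1	0	0	0	1	0	0	1
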