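name	pattern	category
GARE-motif	TCTGTTG	gibberellin
P-box	CCTTTTG	gibberellin
TGACG-motif	TGACG	methyl_jasmonate
CGTCA-motif	CGTCA	methyl_jasmonate
TCA-element	CCATCTTTTT	salicylic_acid
TGA-box	TGACGTAA	auxin
TGA-element	AACGAC	auxin
AuxRR-core	GGTCCAT	auxin
ABRE	ACGTG	abscisic_acid
TC-rich	ATTTTCTTCA	defense_stress
MBS	CAACTG	drought
LTR	CCGAAA	low_temperature
ARE	AAACCA	anaerobic
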