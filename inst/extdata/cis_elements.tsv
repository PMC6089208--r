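name	pattern	category
ABRE	ACGTG	ABA_response
MBS	CAACTG	drought
LTR	CCGAAA	low_temperature
TC-rich	GTTTTCTTAC	defense_stress
WUN-motif	AAATTTCCT	wounding
ARE	AAACCA	anaerobic
GC-motif	CCCCCG	anoxia
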