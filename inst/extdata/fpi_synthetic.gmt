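FPI_POS	synthetic example ferroptosis driver set (not the published signature)	ACSL4	ALOX15	TFRC	NCOA4	SAT1	GLS2	HMOX1	SLC11A2
FPI_NEG	synthetic example ferroptosis suppressor set (not the published signature)	GPX4	SLC7A11	NFE2L2	HSPB1	FTH1	FTL
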