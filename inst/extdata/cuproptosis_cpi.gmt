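CUPROPTOSIS_POS	cuproptosis positive components (as printed)	PDX1	LIAS	LIPT1	DLD	DLAT	PDHA1	PDHB
CUPROPTOSIS_NEG	cuproptosis negative components	MTF1	GLS	CDKN2A
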