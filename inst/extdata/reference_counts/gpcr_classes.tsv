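# Reported putative GPCR counts per receptor class and strain.
strain	gpcr_class	count
Neocallimastix	RHODOPSIN_DICTY_CAR	2
Anaeromyces	RHODOPSIN_DICTY_CAR	1
Piromyces	RHODOPSIN_DICTY_CAR	2
Neocallimastix	CLASS_C	51
Anaeromyces	CLASS_C	24
Piromyces	CLASS_C	32
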