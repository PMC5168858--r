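# Reported sugar-uptake system counts per family and strain.
strain	sugar_family	count
Neocallimastix	MFS	12
Anaeromyces	MFS	5
Piromyces	MFS	7
Neocallimastix	SSS	2
Anaeromyces	SSS	4
Piromyces	SSS	1
Neocallimastix	SWEET	5
Anaeromyces	SWEET	3
Piromyces	SWEET	2
Neocallimastix	ABC_SBP	30
Anaeromyces	ABC_SBP	28
Piromyces	ABC_SBP	10
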