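# GPCR class and N-terminal architecture signature table (editable config).
# kind: class -> receptor class call; flag -> N-terminal architecture flag.
# id_type: interpro matches the InterPro accession column; signature matches
# the member-database signature accession column (e.g. SCOP superfamilies).
signature	id_type	kind	value
IPR017978	interpro	class	CLASS_C
IPR017452	interpro	class	RHODOPSIN_DICTY_CAR
IPR017981	interpro	class	RHODOPSIN_DICTY_CAR
IPR001828	interpro	flag	ANF
IPR011050	interpro	flag	PECTIN_LYASE
IPR012334	interpro	flag	PECTIN_LYASE
IPR006626	interpro	flag	BETA_HELIX
IPR000742	interpro	flag	EGF_LIKE
SSF53850	signature	flag	SBP_TYPE_II
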