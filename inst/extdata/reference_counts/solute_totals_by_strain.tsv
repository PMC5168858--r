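# Reported per-strain totals of small-solute transporter transcripts.
strain	count
Neocallimastix	435
Anaeromyces	312
Piromyces	236
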