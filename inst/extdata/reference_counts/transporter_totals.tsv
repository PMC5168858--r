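# Reported per-strain totals of transcripts encoding transporter components
# in three gut fungal strains (worked-example input for the report aggregator).
strain	count
Neocallimastix	826
Anaeromyces	554
Piromyces	488
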