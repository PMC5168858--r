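# Reported solute-transporter transcripts by substrate super-class, summed
# over the three strains.
substrate	count
SUGARS_METABOLITES	417
DRUGS_LIPIDS	227
INORGANIC_IONS_METALS	339
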