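# Default TC-prefix category map: longest prefix wins.
# Categories: SOLUTE_TRANSPORT, PROTEIN_BIOGENESIS_SECRETION, NUCLEAR_TRANSPORT,
#   PEROXISOMAL_IMPORT, ORGANELLE_IMPORT, OTHER.
# Substrates (solute transport only): SUGARS_METABOLITES, DRUGS_LIPIDS,
#   INORGANIC_IONS_METALS; UNASSIGNED elsewhere.
# Note: the SSS sugar-symporter family is listed here under 2.A.2 to match the
# reference configuration, although that TC number canonically denotes the
# glycoside-pentoside-hexuronide family; edit this file to override.
tc_prefix	category	substrate	sugar_family	note
2.A.1	SOLUTE_TRANSPORT	SUGARS_METABOLITES	MFS	major facilitator superfamily sugar porters
2.A.1.2	SOLUTE_TRANSPORT	DRUGS_LIPIDS	NONE	Drug:H+ antiporter DHA1
2.A.1.3	SOLUTE_TRANSPORT	DRUGS_LIPIDS	NONE	Drug:H+ antiporter DHA2
2.A.1.19	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	organic cation porters
2.A.2	SOLUTE_TRANSPORT	SUGARS_METABOLITES	SSS	solute sodium symporter family (see header note)
2.A.123	SOLUTE_TRANSPORT	SUGARS_METABOLITES	SWEET	SWEET sugar transporters
3.A.1	SOLUTE_TRANSPORT	SUGARS_METABOLITES	ABC_SBP	ABC uptake systems with substrate-binding proteins
3.A.1.201	SOLUTE_TRANSPORT	DRUGS_LIPIDS	NONE	ABC drug exporters (MDR)
3.A.1.211	SOLUTE_TRANSPORT	DRUGS_LIPIDS	NONE	ABCA lipid flippases
2.A.66	SOLUTE_TRANSPORT	DRUGS_LIPIDS	NONE	multi antimicrobial extrusion (MATE)
3.A.3.8	SOLUTE_TRANSPORT	DRUGS_LIPIDS	NONE	P-type ATPase lipid flippases
2.A.18	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	amino acid/auxin permeases
2.A.22	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	neurotransmitter:sodium symporters
2.A.79	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	threonine/serine exporters
2.A.85	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	aromatic acid exporters
1.A.11	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	ammonia channels
2.A.50	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	glycerol uptake
1.A.16	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	formate/nitrite channels
2.A.7.11	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	nucleotide-sugar transporters
2.A.7.12	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	nucleotide-sugar transporters
2.A.29	SOLUTE_TRANSPORT	SUGARS_METABOLITES	NONE	mitochondrial (hydrogenosomal) carriers
1.A.1	SOLUTE_TRANSPORT	INORGANIC_IONS_METALS	NONE	voltage-gated ion channels
2.A.40	SOLUTE_TRANSPORT	INORGANIC_IONS_METALS	NONE	chloride channels
3.A.2	SOLUTE_TRANSPORT	INORGANIC_IONS_METALS	NONE	V-type ATPases
3.A.3	SOLUTE_TRANSPORT	INORGANIC_IONS_METALS	NONE	P-type ATPases
2.A.59	SOLUTE_TRANSPORT	INORGANIC_IONS_METALS	NONE	arsenite transporters
1.A.26	SOLUTE_TRANSPORT	INORGANIC_IONS_METALS	NONE	magnesium transporters
2.A.5	SOLUTE_TRANSPORT	INORGANIC_IONS_METALS	NONE	zinc/iron permeases
2.A.89	SOLUTE_TRANSPORT	INORGANIC_IONS_METALS	NONE	vacuolar iron transporters
3.A.5	PROTEIN_BIOGENESIS_SECRETION	UNASSIGNED	NONE	general secretory pathway (Sec)
1.A.33	PROTEIN_BIOGENESIS_SECRETION	UNASSIGNED	NONE	heat shock protein channels
3.A.16	PROTEIN_BIOGENESIS_SECRETION	UNASSIGNED	NONE	ER retrotranslocon
1.F.1	PROTEIN_BIOGENESIS_SECRETION	UNASSIGNED	NONE	SNARE vesicle fusion
1.A.55	PROTEIN_BIOGENESIS_SECRETION	UNASSIGNED	NONE	synaptic vesicle calcium channels
1.A.31	PROTEIN_BIOGENESIS_SECRETION	UNASSIGNED	NONE	annexin-like proteins
1.I.1	NUCLEAR_TRANSPORT	UNASSIGNED	NONE	nuclear pore complex
3.A.18	NUCLEAR_TRANSPORT	UNASSIGNED	NONE	nuclear mRNA export
3.A.22	NUCLEAR_TRANSPORT	UNASSIGNED	NONE	nuclear export complexes
9.A.50	NUCLEAR_TRANSPORT	UNASSIGNED	NONE	RNA maturation/export factors
3.A.20	PEROXISOMAL_IMPORT	UNASSIGNED	NONE	peroxisomal import machinery
1.B.33	ORGANELLE_IMPORT	UNASSIGNED	NONE	mitochondrial outer membrane import (TOM)
1.B.8	ORGANELLE_IMPORT	UNASSIGNED	NONE	mitochondrial outer membrane porins
3.A.8	ORGANELLE_IMPORT	UNASSIGNED	NONE	mitochondrial inner membrane import (TIM)
3.A.9	ORGANELLE_IMPORT	UNASSIGNED	NONE	chloroplast/plastid envelope import
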