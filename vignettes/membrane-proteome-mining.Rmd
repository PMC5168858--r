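---
title: "Mining membrane proteomes from strand-specific transcriptomes"
author: "membraneMiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining membrane proteomes from strand-specific transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membraneMiner)
```

## The problem

Anaerobic gut fungi (Neocallimastigomycota) are powerful lignocellulose
degraders, but they lack high-quality genome assemblies; what is available
for strains such as *Neocallimastix*, *Anaeromyces* and *Piromyces* are
strand-specific de novo transcriptome assemblies. Their membrane proteome —
sugar transporters, drug extruders, ion pumps, receptors — is of direct
biotechnological interest, yet none of it is annotated out of the box.

`membraneMiner` implements a desk-scale mining pipeline over such
transcriptomes:

1. **ORF extraction** — all open reading frames in six frames; the longest
   ORF represents each transcript.
2. **Topology profiling** — signal-peptide and transmembrane (TM) calls
   parsed from TMHMM/SignalP/Phobius-style predictor output, or produced by
   a built-in hydropathy fallback.
3. **The funnel** — each transcript is binned as antisense, soluble,
   secreted, bitopic membrane or polytopic membrane.
4. **GO-role binning** — membrane proteins are assigned one of five
   functional roles by keyword precedence.
5. **Transporter classification** — TCDB homology with a reciprocal 70%
   coverage filter, an inclusive 10^-3^ e-value gate, smallest-E best hit,
   five-tier TC-identity parsing and category/substrate/sugar-family
   binning.
6. **GPCR discovery** — keyword entry filter, a 7–9 TM gate, N-terminal
   region delimitation and receptor-class / domain-architecture calls.

A synthetic-data generator plants a fully known classification into mock
transcripts and annotation files so that every stage is testable end to end
without any external database.

## Stage models and the decisions behind them

### ORF extraction

Every ATG-to-in-frame-stop ORF is reported in all six frames, plus
open-ended ORFs truncated by the transcript ends (flagged `partial`),
because de novo assemblies are frequently 5'- or 3'-truncated. ORF length is
counted in codons with the terminal stop included; the default minimum is 50
codons, a conventional transcriptome cutoff (no canonical value exists for
this step). Ties in length are broken by frame order (+1,+2,+3,−1,−2,−3)
then start coordinate, making the representative (longest) ORF
deterministic. Choosing the longest ORF as the transcript's protein is the
standard default when no expression or homology evidence dictates otherwise.

Antisense transcripts are recognised from the annotation reading frame: a
transcript whose best annotation hit lies in frame −1/−2/−3 of the
strand-specific assembly is treated as non-coding antisense. A transcript
with a negative-frame representative ORF but *no* annotation at all is not
flagged — without an annotation frame there is no evidence either way.

### Topology

Predictor output is parsed from three dialects (TMHMM short, SignalP short
tabular, Phobius short tabular). Where several predictors cover the same
protein, the default combination is the **union**: TM segment sets are
interval-unioned (residue-coverage semantics, so overlapping or adjacent
segments merge), and a signal peptide is called if any source calls one,
with the cleavage site taken as the maximum over sources. Union maximises
sensitivity, which matches an inclusive signal-peptide-and/or-TM funnel;
`intersection` and `priority` modes exist for sensitivity analysis.

A TM segment whose start lies at or before the signal-peptide cleavage site
is treated as the signal peptide itself, not a membrane anchor — predictors
routinely call hydrophobic signal sequences as helices. The **non-cleaved TM
count** (segments starting after the cleavage site) is therefore the count
the funnel uses.

The fallback predictor is a deliberately simple Kyte–Doolittle sliding
window (width 19 residues, mean hydropathy threshold 1.6 — standard
hydropathy heuristics, configurable). Maximal runs of above-threshold
windows become TM segments; a run starting within the first 30 residues
followed within 10 residues by a small residue (A/G/S/T/C) is additionally
reported as a signal-peptide candidate. Window means are compared with a
10^-9^ epsilon so that windows sitting exactly on the threshold resolve
identically regardless of floating-point summation order. The fallback does
not reproduce the TMHMM/SignalP probabilistic models and is only meant to
let the pipeline run with zero annotation files.

### The funnel

With k = non-cleaved TM count of the representative protein:
antisense → `ANTISENSE_NONCODING`; k = 0 with SP → `SECRETED`; k = 0
without SP → `SOLUBLE`; k = 1 → `BITOPIC_MEMBRANE`; k ≥ 2 →
`POLYTOPIC_MEMBRANE`. Transcripts without any topology profile are binned
`SOLUBLE` but flagged `no_profile`, keeping the funnel a strict partition
(there is no separate "unannotated" arm). "Trafficked" means SP and/or at
least one TM; antisense transcripts stay in the denominator but never in the
trafficked numerator. Each transcript is counted exactly once, through its
representative ORF.

### GO roles

Membrane proteins are binned by case-insensitive keyword matching on GO term
text, in strict precedence: *Transport* ("transport", "symport", "v-type
atpase") > *Sensing and signaling* ("receptor", "signal", "sensor") >
*Catalysis* (final whitespace-delimited word ends in "-ase") > *Other* (any
other annotation) > *Unknown* (no GO term). A protein with several matching
functions is binned once, at the highest precedence — an ABC transporter
with both transport and ATPase annotations is *Transport*. This is keyword
parsing, not ontology-graph reasoning; the "-ase" suffix rule is blunt by
design and rare false positives (terms ending in "...base") are accepted and
documented. Five bins are reported, keeping *Unknown* distinct from *Other*.

### TCDB transporters

All transcripts are eligible regardless of predicted topology: peripheral
transporter subunits and beta-barrels lack canonical hydrophobic helices and
would otherwise be missed. A hit survives only when the alignment span
covers at least 70% of the query **and** at least 70% of the subject
(coverage is computed from the alignment span, not identities; the threshold
is inclusive). Among surviving hits with e-value ≤ 10^-3^ (inclusive — the
e-value gates in this package are uniformly "≤"), the smallest-E hit wins;
ties break by larger bit score, then lexicographic subject id, so the result
is order-independent. The TC identity tag (class.subclass.family, optionally
.subfamily.system; at least three tiers) is parsed from the subject id or
description, and binned by **longest-prefix** lookup in an editable category
map — so a Drug:H⁺-antiporter rule on `2.A.1.2` outranks the generic MFS
sugar rule on `2.A.1`. Unmatched tags fall into category `OTHER`.

The shipped map encodes one rule per TC number of the reference
configuration, grouped into six functional categories (solute transport,
protein biogenesis/secretion, nuclear transport, peroxisomal import,
organelle import, other), three substrate super-classes for solute
transporters (sugars/metabolites, drugs/lipids, inorganic ions/metals) and
four sugar-uptake families (MFS, SSS, SWEET, ABC with substrate-binding
proteins). One deliberate quirk is preserved: the SSS sugar-symporter family
is mapped to TC `2.A.2` to follow the reference configuration, although that
number canonically denotes a different family; the map is configuration, so
users can override it.

### GPCRs

A protein is a candidate iff an annotation description contains "GPCR" or
"G-protein coupled receptor" (case-insensitive) **and** its raw TM count is
between 7 and 9 inclusive. The gate uses the raw count, before
signal-peptide discounting: the upper bound of 9 exists precisely to
tolerate hydrophobic signal sequences called as extra helices. The
heptahelical bundle is taken as the **7 most C-terminal** TM segments
(class C receptors carry seven carboxy-terminal helices; when 8–9 segments
are predicted the extra N-terminal ones are assumed to be signal sequences),
and the N-terminal extracellular region runs from residue 1 to just before
the bundle. Domains count as N-terminal only when wholly contained (end
strictly before the bundle start) — boundary-spanning domains are excluded
for determinism.

Receptor class comes from signatures anywhere in the protein: `IPR017978` →
class C (glutamate-receptor-like); `IPR017452`/`IPR017981` →
rhodopsin-like / slime-mold cAMP receptor (dicty-CAR); both present →
class C with an explicit conflict flag (never silent). Architecture flags
come only from N-terminal domains: `IPR001828` → ANF,
`IPR011050`/`IPR012334` → pectin lyase fold, `IPR006626` → parallel
beta-helix, `IPR000742` → EGF-like, SCOP superfamily `SSF53850` → SBP
type II. The signature table is shipped as editable TSV.

## The synthetic-data generator

`generate_transcriptome()` plants one ORF per transcript whose translated
protein carries the features its class implies: 21-residue stretches drawn
from a strongly hydrophobic alphabet (L/I/V/F/A-rich) for each planted TM
segment — strong enough that the fallback predictor finds them too — an
N-terminal signal-peptide-like stretch for secretory classes, and polar
bodies otherwise. Antisense transcripts carry the ORF on the reverse strand.
`emit_mock_annotations()` writes per-strain FASTA plus mock TMHMM, Phobius,
SignalP, TCDB-alignment and InterProScan-style files in exactly the dialects
the parsers read; mock TMHMM renders a planted signal peptide as an extra
N-terminal helix (as the real tool tends to), which exercises both the
SP-discount rule and the widened GPCR gate.

Two generator-internal details are worth knowing. First, a stop codon is
planted immediately upstream of each ORF's ATG, and polar runs carry ~8%
hydrophobic singletons (L/I/V/M): the singletons are what seed stop codons
in the +1-shifted reading frame — a purely polar alphabet has no codon with
TA/TG at positions 2–3, so without them a frame-shifted open-ended ORF
spanning the whole transcript would outrank the planted ORF. A
post-generation check re-extracts ORFs and resamples the rare transcript
whose random flanks still allow a longer competitor, so the representative
ORF is always the planted one. Second, annotation noise corrupts exactly one
field per selected record (a TM count, an SP call, an e-value pushed across
the 10^-3^ boundary, a coverage span, a GO role keyword, or a signature id)
and always changes the record; files stay parseable, separating parse
robustness from classification robustness.

The default class mixture makes roughly a fifth of transcripts trafficked,
about a third of those fully secreted, a 5% antisense arm, transporters
spread over every category the classifier knows, and a thin tail of GPCR
architectures dominated by class C — a plausible gut-fungal profile at a
glance. The generator does **not** emulate realistic codon usage, the
extreme AT-richness of Neocallimastigomycota, expression levels, assembly
chimerism or sequencing error; a clean round-trip therefore demonstrates
that the pipeline's logic is faithful, not that real predictor output is
this well-behaved.

## Numerical choices, reproducibility and test scale

* All e-value and coverage gates are inclusive at their boundary; e-values
  equal to 10^-3^ and coverage of exactly 70% pass.
* Best-hit and ORF orderings carry total, documented tie-breaks; reports are
  byte-identical across runs from the same config and seed, and a manifest
  records thresholds and input checksums.
* The same seed gives byte-identical generator output; the corruption stream
  uses its own seed (config seed + 1 by default).
* Every total printed in a report flows through one aggregator
  (`add_margin_totals()`), so each summary figure is a recount of the
  underlying per-strain table.

The shipped test suite validates the stages against independent brute-force
oracles (a positional six-frame scanner, an exhaustive filter-sort for best
hits, a direct window-by-window hydropathy recomputation), and runs a full
noiseless round-trip at 3 strains × 1000 transcripts — every report table
must equal the planted tallies exactly — plus a noise sweep
(0 → 0.1 → 0.3 → 0.5 at 500 transcripts, two seeds) in which mean label
recovery must be non-increasing. These problem sizes keep the whole suite
around a minute on one CPU while leaving the binomial sampling error of the
class mixture far below any tested margin.

## Known limitations

* The fallback topology predictor is a hydropathy heuristic; on real
  proteins it under-calls marginally hydrophobic helices and should not be
  used where real predictor output is available.
* GO-role binning is keyword matching on term names; it inherits the
  bluntness of the "-ase" suffix rule and does not traverse the ontology.
* TCDB categorisation is only as complete as the category map; tags not
  covered by a prefix rule land in `OTHER` rather than being guessed.
* The pipeline classifies one representative ORF per transcript; a chimeric
  transcript encoding two proteins contributes only its longest ORF.
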