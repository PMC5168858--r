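Package: membraneMiner
Title: Membrane-Proteome Mining from Strand-Specific Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines membrane proteins from assembled strand-specific
    transcriptomes of anaerobic gut fungi (and similar organisms lacking
    genome assemblies). Extracts all open reading frames in six frames,
    derives per-protein topology profiles from TMHMM-, SignalP- and
    Phobius-style predictor outputs (or a built-in Kyte-Doolittle fallback),
    funnels transcripts into antisense / soluble / secreted / bitopic /
    polytopic classes, bins membrane proteins into functional roles by
    GO-keyword precedence, classifies transporters by TCDB homology with a
    reciprocal 70 percent coverage filter and five-tier TC-identity parsing,
    and discovers G-protein coupled receptor candidates by keyword plus a
    7-9 transmembrane-segment gate with N-terminal domain-architecture
    analysis. Ships a synthetic-transcriptome generator with planted ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
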