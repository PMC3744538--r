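Package: plkscreen
Title: Sequence-Motif Screening for Candidate Polo-Like Kinase 1 Substrates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Proteome-wide discovery screen for candidate substrates of
    polo-like kinase 1 (Plk1). Compiles degenerate short linear motifs (the
    Plk1 kinase consensus phosphorylation motif and the polo-box-domain
    recognition motif), scans protein sequences with an exhaustive sliding
    window under an identity or BLOSUM62 substitution scoring mode, groups
    motif-positive proteins into annotation-term clusters scored with an
    upper-tail hypergeometric by-chance probability, and orchestrates the
    staged filter cascade (motif presence, similarity threshold, annotation
    enrichment, polo-box docking motif, cell-cycle phase and cancer
    annotation) that yields a ranked, phase-annotated candidate substrate
    table. Includes a synthetic proteome and annotation generator with
    planted ground truth for end-to-end validation, plus FASTA/GMT/TSV
    readers and writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
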