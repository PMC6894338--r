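Package: methmark
Title: CpG-Island Detection, In-Silico CoBRA, TCS Motif Scanning and
    Methylation-Stratified Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for promoter hypermethylation biomarker analysis of
    the kind used to characterise epigenetically silenced tumour
    suppressors. Detects CpG islands under the classical composition
    criteria (length, G+C content, observed/expected CpG ratio),
    simulates bisulfite conversion and combined bisulfite restriction
    analysis (CoBRA) including degenerate-primer validation, in-silico
    PCR and methylation-dependent restriction digests, quantifies
    per-CpG methylation beta values from simulated pyrosequencing
    reads, scans 3'UTR sets for the degenerate translation control
    sequence (TCS) consensus with windowed duplicate detection,
    performs Kaplan-Meier / log-rank survival analysis with mean-split
    and best-cutoff biomarker dichotomisation implemented from first
    principles, and places CRISPR SpCas9 guides relative to a
    transcription start site. Seeded generators produce every input
    class with machine-readable planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    survival,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
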