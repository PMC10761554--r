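Package: damagetx
Title: Transcriptional Response to Bulky DNA Damage: Simulation and
    Comparative Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the transcriptional response to bulky,
    transcription-blocking DNA damage (UV photoproducts, cisplatin and
    BPDE adducts). Provides per-condition differential-expression
    classification, cross-condition consistency scoring, gene-architecture
    stratification (length, GC content, exon fraction), strand-specific
    damage/repair read coverage over gene bodies, and promoter motif
    enrichment with an empirical permutation null. A forward simulator of
    the damage, repair and transcription-suppression causal model generates
    fully ground-truthed synthetic studies so that every analysis stage is
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
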