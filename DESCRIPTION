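Package: hrepipe
Title: Integrative ChIP-Seq and Expression Analysis of HRE-Bound Gene Programs
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies transcription-factor-bound genes into responsive and
    unresponsive sets by integrating ChIP-Seq peak tables with expression time
    courses. Provides IUPAC consensus scanning for the hypoxia-response-element
    core motif (RCGTG) in promoter windows, peak filtering, merging and
    nearest-TSS assignment, TPM normalisation and fold-change gene filters,
    two-level Ward hierarchical clustering with a permutation test for cluster
    separation, cumulative-binomial motif enrichment against GC- and
    length-matched background, and a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
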