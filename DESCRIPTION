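Package: drnalen
Title: Differential Read-Length Analysis for Nanopore Direct RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical testing of per-transcript RNA read-length changes in
    nanopore direct RNA-Seq, built around a linear mixed model with a
    per-library random intercept (with plain linear-model and Wilcoxon
    alternatives) and Benjamini-Hochberg FDR control. Includes a
    seed-reproducible simulation engine for type-I-error and power evaluation
    under a transcript-shortening model, and read-geometry metrics computed
    from transcriptome alignments: aligned read spans, 20-bin meta-length,
    transcription start site calls from 5' end density within the 5' UTR, and
    nucleotide composition around read 5' ends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    lme4,
    lmerTest,
    stats,
    utils,
    jsonlite,
    Rsamtools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
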