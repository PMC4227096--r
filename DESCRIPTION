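Package: msccflow
Title: Methylome, Splicing and Behavioral Analysis for Opioid-Exposure Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a genome-wide DNA methylation and transcriptome analysis
    workflow for two-group (drug vs. vehicle) mouse studies built on the
    methyl-sensitive cut-counting (MSCC) assay: per-CCGG-site methylation
    quantification with spike-in normalization and a depth filter, gene-feature
    and CpG-island/shore annotation with TSS meta-profiles, differentially
    methylated region calling over 200-bp sliding windows and CpG-island units
    by paired t-tests, a binomial junction-read model for exon-skipping
    percent-spliced-in (Psi) estimation and Bayes-factor scoring, promoter
    methylation-expression integration, qPCR relative-quantification
    arithmetic, and conditioned-place-preference behavioral scoring. A
    synthetic-data generator with known ground truth (toy genome, methylomes,
    MSCC tag counts, expression, junction reads, behavioral sessions) supports
    end-to-end validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
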