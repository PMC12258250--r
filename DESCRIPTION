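Package: tfscan
Title: Multiomic Scoring and Benchmarking of Transcription Factor
    Binding Sites in Promoters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans promoter DNA with JASPAR-style position weight
    matrices and augments the motif score with empirical log-likelihood
    scores derived from genome-scale regulatory evidence: TSS-proximal
    CAGE peaks, TF-gene expression correlation, ChIP-Seq metaclusters,
    open-chromatin (ATAC-Seq) peaks, eQTL effect magnitudes, CpG
    observed/expected ratio, and conserved-element proximity. Feature
    scores are summed into a combined affinity score that is calibrated
    with empirical p-values against a background promoter corpus. Also
    provides a CAGE-like TSS peak caller for coverage tracks, a
    reproducible synthetic-fixture generator (genomes, motif implants,
    enriched feature tracks), and a benchmarking suite with matched
    true-negative sampling, rank-based ROC/AUROC, an exhaustive
    feature-combination search, and paired t-test model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
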