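Package: fracloc
Title: Subcellular Localization from Differential-Centrifugation LFQ Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of label-free quantitative (LFQ) spatial
    proteomics obtained by differential centrifugation (LOPIT-DC style
    designs): MaxQuant-dialect protein-group filtering, left-censored
    imputation, pairwise fraction statistics with false-discovery control,
    self-organizing-map clustering of standardized fraction profiles with
    quality-based merging and traveling-salesman display ordering,
    Fisher-exact compartment enrichment labeling, and per-protein
    localization confidence scores. Also implements coverage-based gene-model
    quality-control procedures (N50/ExN50 assembly statistics, split-gene and
    short-ORF read-coverage classification, missense peptide-impact
    proportions, hit-coverage binning and precision/variant-rate summaries)
    and a fully parameterized synthetic-data generator with planted ground
    truth so every stage is testable without raw data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
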