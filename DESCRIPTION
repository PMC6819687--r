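Package: cohortCNV
Title: Copy Number Variant Discovery from SNP-Array Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for discovering copy number variants
    (CNVs) in SNP-array cohorts. Provides genotype- and signal-level quality
    control, a six-state hidden Markov model that segments per-sample Log R
    Ratio / B allele frequency tracks into copy-number calls with
    distance-aware transitions and population-B-allele-frequency-weighted
    emissions, population-level CNV region (CNVR) construction with
    cumulative-frequency boundary trimming, read-depth cross-validation from
    sliding-window counts with GC correction, and concordance / QTL / gene
    overlap analytics with hypergeometric term enrichment. A synthetic cohort
    generator with known truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: CopyNumberVariation, HiddenMarkovModel, SNP, QualityControl,
    Coverage
RoxygenNote: 7.3.3
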