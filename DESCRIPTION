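Package: defensinCNV
Title: Fine-Mapping and Evolutionary Analysis of Multiallelic Beta-Defensin Copy Number Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-mapping multiallelic copy-number-variable (CNV)
    blocks from tiling array comparative genomic hybridization (aCGH) data by
    correlating per-probe log2 intensity ratios with independently assayed copy
    number, for localizing CNV breakpoints with a Gaussian-emission hidden
    Markov model, for converting paralog ratio test (PRT), droplet digital PCR
    (ddPCR) and quantitative PCR measurements into integer diploid copy-number
    calls via principal-component integration, for testing positive selection
    between tandem paralogs versus alleles with a Jukes-Cantor-corrected
    McDonald-Kreitman test, and for bracketing the age of a duplication from
    diagnostic retroelement insertions across related lineages. A synthetic
    cohort generator reproduces the statistical structure of human-like and
    macaque-like beta-defensin CNV cohorts so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    rlang,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, aCGH, HiddenMarkovModel, Genetics, Evolution
RoxygenNote: 7.3.3
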