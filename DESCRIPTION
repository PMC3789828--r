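Package: riboshift
Title: Comparative Analysis of Translatome and Transcriptome Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for paired ribosome-profiling (RPF) and
    mRNA-seq count data across species and conditions. Provides median-of-ratios
    normalization, log2 fold changes, a negative-binomial differential
    expression test with moderated dispersion, concordance analysis of
    translational and mRNA-abundance regulation, the translational-component
    score, cross-species ortholog fold-change correlation, four-way ortholog
    expression divergence with a shuffle null, sample-level PCA, ribosome
    resource-allocation fractions, and a negative-binomial count simulator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
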