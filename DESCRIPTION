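Package: neoclonal
Title: Neoantigen Clonality and Tumour Immune Context Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-tumour summarisation of predicted MHC class I neoepitopes
    (binder counts, binder-weighted variant allele frequency, a count-normalised
    Clonality Score and alternative clonality metrics), geometric-mean composite
    immune gene signature scoring from bulk expression, a Spearman and partial
    Spearman correlation battery with false discovery rate control, median-split
    four-phenotype immune classification with unsupervised-clustering validation,
    public-neoepitope population coverage analysis for shared vaccine design, and
    immune-context-dependent Cox survival modelling. Includes a synthetic cohort
    generator that plants known clonality-immune correlation structure, VAF
    mixtures under tumour purity, shared peptide pools, and interaction hazards
    so that every analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    mclust,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
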