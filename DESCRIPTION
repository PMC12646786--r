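Package: cytocline
Title: Cytonuclear Co-Introgression Analysis for Hybrid Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting co-introgression of nuclear-encoded
    chloroplast-interacting genes with the chloroplast genome across
    hybrid-zone transects. Fits maximum-likelihood geographic clines
    (sigmoid with optional exponential tails and frequency scaling) to
    chlorotype and local-ancestry data, compares gene clines to
    chloroplast and nuclear reference clines with constrained-model
    likelihood-ratio tests, associates chlorotype with climate gradients
    by Firth bias-reduced logistic regression, scans chloroplast
    alignments for fixed inter-specific differences with codon-level
    effect classification and neighbour-joining polarization, and
    estimates broad-sense heritability and cytonuclear interaction
    effects on traits with linear mixed models. A synthetic-data
    generator with recorded ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    lme4,
    lmerTest,
    lhs,
    rlang,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
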