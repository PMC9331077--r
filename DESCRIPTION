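Package: duplexmut
Title: Downstream Analysis of Duplex Sequencing Mutagenesis Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clonality-aware mutation-frequency estimation, mutation spectra,
    trinucleotide signature matching, multivariate sample classification, and
    benchmark-dose modelling for error-corrected duplex sequencing mutagenesis
    panels. Includes a seeded synthetic-cohort generator that emulates a
    dose-response study of a genotoxicant across a multi-target genomic panel
    (dose-dependent mutation frequencies, exposure-specific trinucleotide
    spectra, clonal expansion, genic/intergenic and chromatin modifiers), so
    that every downstream stage can be exercised and validated without access
    to raw sequencing data. Statistical machinery covers binomial generalized
    linear models with Holm-Sidak-adjusted Wald contrasts, Monte Carlo
    contingency tests of spectra, cosine similarity against signature
    catalogs, binomial-distance non-metric multidimensional scaling, Mantel
    tests, nearest-shrunken-centroid classification with a Gaussian
    discriminant, and equal-weight model-averaged benchmark doses for
    continuous endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
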