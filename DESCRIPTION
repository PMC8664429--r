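Package: gptrial
Title: Genomic Prediction and Sparse-Testing Cross-Validation for Two-Site Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for early-generation genomic prediction in multi-site plant
    breeding programs. Fits single-site and two-site genomic-kernel mixed models
    by restricted maximum likelihood (average-information updates with
    expectation-maximisation fallback), supporting GBLUP (linear kernel) and
    reproducing kernel Hilbert space (Gaussian kernel) genotype covariances with
    data-driven bandwidth selection, genotype-by-site interaction terms and
    site-specific residual variances. Provides trial-level repeatability and
    global broad-sense heritability on an entry-mean basis, four
    cross-validation and sparse-testing schemes scored by predictive ability,
    eta-squared attribution of predictive-ability variation, and a simulator for
    two-site lattice trials with known genetic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
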