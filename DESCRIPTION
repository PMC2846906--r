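Package: momentKPLS
Title: Statistical-Moment Dimensionality Reduction and Kernel PLS
    Classification for SELDI-TOF Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies high-dimensional SELDI-TOF-style mass-spectrometry
    profiles. Raw per-sample spectra are aligned on the sorted union of
    observed m/z values, m/z rows with missing intensities are discarded,
    rows are filtered by a two-sample t-test, and the surviving rows are
    partitioned into fixed-width windows that are each summarized by up to
    four statistical moments (mean, variance, skewness, kurtosis). The
    resulting low-dimensional features are classified with kernel partial
    least squares (polynomial kernel, Gram-matrix centering, NIPALS-style
    latent-variable extraction with deflation). Includes repeated stratified
    five-fold cross-validation, per-class proportional hold-out validation
    and leave-one-out validation with sensitivity, specificity, accuracy and
    Matthews correlation reporting, plus a synthetic spectrum generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
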