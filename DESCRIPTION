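Package: ramancell
Title: Raman Spectral Preprocessing and PCA-LDA Classification of Single Cells
Version: 0.1.0
Authors@R: person("ramancell", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A chemometrics pipeline for classifying single-cell Raman
    spectra. Implements spectral preprocessing (range cutting,
    Savitzky-Golay smoothing, iterative anchored-minima baseline
    correction, vector normalization), per-fold principal component
    feature extraction, linear discriminant classification by minimum
    Mahalanobis distance, stratified grouped k-fold cross-validation with
    confusion-matrix metrics, plateau-based selection of the number of
    principal components, biomolecular sub-range analysis, and a seeded
    synthetic Raman spectrum generator for end-to-end validation of the
    pipeline without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
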