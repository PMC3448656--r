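Package: p3source
Title: Source-Space Analysis of P3b Oddball EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for source-space analysis of
    two-stimulus (oddball) P3b EEG experiments: Infomax independent
    component analysis, equivalent current dipole localization in a
    four-shell spherical head model, Morlet-wavelet event-related
    spectral perturbation (ERSP) and inter-trial coherence (ITC)
    measures, cross-subject K-means clustering of independent
    components, and permutation group statistics with false discovery
    rate and Bonferroni control.  Includes a synthetic dipolar-EEG
    cohort generator with known ground truth so that every stage of the
    pipeline can be verified without access to patient recordings, and
    regression-based demographic correction of PASAT scores with
    extreme-tertile group construction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
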