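Package: iscagree
Title: Inter-Subject Synchronization in fMRI via the ICC Agreement Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise inter-subject correlation (ISC) analysis of multi-subject
    fMRI using the intraclass correlation agreement index ICC(A,M) with its
    asymptotic (delta-method) standard error, significance mapping against a
    Fourier phase-randomization surrogate null with weak false discovery rate
    control, stationarity screening (KPSS, ADF, lagged-correlation mixing
    diagnostics), clustering of region-of-interest mean time courses into
    response networks, Fisher-Z connectivity summaries, and partial-correlation
    tests of connectivity against salivary cortisol. Includes a synthetic BOLD
    data generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
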