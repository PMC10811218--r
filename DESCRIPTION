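Package: strokemi
Title: Motor-Imagery EEG Decoding for Acute Stroke Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for storing, simulating, validating and decoding left- versus
    right-hand motor-imagery (MI) electroencephalography recorded from acute
    stroke patients. Implements the dataset's on-disk schema (MAT level-5 trial
    tensors, EDF exports, an EEG-BIDS style tree, the 33-channel 10-10 montage),
    the preprocessing chain (baseline removal, FIR and zero-phase Butterworth
    band-pass filtering, marker-based epoching), qualitative validation
    (event-related desynchronization curves, Morlet time-frequency maps, band
    power topographies) and four decoding pipelines: CSP+LDA, filter-bank
    CSP+SVM, tangent-space LDA fused with Fisher geodesic filtering + minimum
    distance to Riemannian mean, and an optimal time-window/filter-bank
    Riemannian decoder that selects windows and bands by backtracking search,
    reduces block tangent features by local tangent space alignment and
    classifies by a discriminant filter with nearest class centroid. A seeded
    synthetic stroke-cohort generator with ground-truth sidecars allows every
    analysis to run without the deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    e1071,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
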