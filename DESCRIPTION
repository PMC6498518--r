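Package: apnet
Title: Resting-State EEG Connectivity and Graph Analysis for Absolute Pitch Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a resting-state EEG functional connectivity pipeline in
    the study of absolute pitch and autistic traits in musicians: multitaper
    cross-spectral estimation and weighted phase lag index (wPLI) connectivity
    per frequency band, minimum-spanning-tree-seeded density thresholding,
    graph metrics (clustering, characteristic path length, small-worldness)
    normalized against degree-preserving random references, group statistics
    with a successive-threshold criterion and permutation edge tests with FDR
    control, and behavioral scoring of pitch-adjustment trials (MAD, SDfoM,
    z-scores), Autism Spectrum Quotient questionnaires and pitch identification
    screening. Includes a fully synthetic cohort generator (phase-coupled
    oscillations over 1/f noise plus behavioral records) with known ground
    truth so the entire pipeline is testable without access to subject data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
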