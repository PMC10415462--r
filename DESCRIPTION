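Package: restcouple
Title: Resting-State EEG-fMRI Source Connectivity Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-condition (inside- vs.
    outside-MR scanner) resting-state EEG and fMRI group studies. Provides a
    synthetic two-group cohort generator with planted band-limited source
    coupling and scanner artifacts, gradient-artifact template subtraction and
    optimal-basis-set ballistocardiogram removal, DICS beamformer source
    reconstruction from band-wise cross-spectral densities, imaginary-coherency
    connectivity and node-strength maps, confound-regressed seed-based fMRI
    correlation maps, permutation GLM inference with threshold-free cluster
    enhancement and familywise/false-discovery-rate correction, and a
    sensor-shuffling surrogate test for cross-modal spatial concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
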