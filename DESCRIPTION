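Package: nocistate
Title: Unsupervised Anesthesia-State Analysis of Nociceptive-Evoked ECoG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying latent anesthesia states from stimulus-locked
    multichannel electrocorticography (ECoG). The package extracts
    nociceptive-evoked spectral features (laser-evoked potentials and gamma-band
    oscillations via short-time Fourier analysis), permutation entropy, and
    permutation cross-mutual information from peri-stimulus epochs; assembles a
    per-trial feature matrix; identifies latent states by repeated k-means with
    Hungarian label alignment, majority-vote consensus, leave-one-out subject
    validation, and subject-level bootstrap selection of the cluster number; and
    quantifies redundancy between feature families with a Kraskov k-nearest
    neighbor mutual-information "relative information sharing" statistic. A
    synthetic-data module generates four-state ECoG cohorts with ground-truth
    labels so the whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
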