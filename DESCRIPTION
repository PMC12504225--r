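Package: gaitssl
Title: Self-Supervised Transformer Pre-Training for Joint Moment
    Estimation from Gait Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage estimation of lower-limb joint moments from
    joint-angle gait waveforms: a Transformer auto-encoder is pre-trained
    on unlabeled multichannel kinematics by masked reconstruction, then
    fine-tuned with frozen early layers to map joint angles to joint
    moments (N.m/kg). Includes a synthetic multi-subject, multi-speed
    gait generator with a known angle-to-moment forward model, windowing
    and standardization utilities, label-efficiency benchmarking,
    peak/valley error analysis, and cross-joint transfer matrices, so the
    full pipeline can be exercised at desk scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
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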