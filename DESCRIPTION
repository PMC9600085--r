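Package: ldctadapt
Title: Low-Dose CT Noise Modelling and Dosimetric Evaluation for Adaptive Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the dosimetric impact of low-dose CT scanning
    protocols on adaptive proton therapy at desk scale. Calibrates a per-HU
    Gaussian noise lookup table from paired standard/low-dose scans, fits the
    tube-current scaling of the noise, synthesizes low-dose CT volumes with a
    reassignment QA check, computes proton dose with an analytic pencil-beam
    surrogate (HU to relative stopping power, Siddon water-equivalent path
    length tracing, Bragg depth-dose, dose-influence matrix and beamlet
    re-weighting), and quantifies differences with DVH metrics, the Dice
    coefficient and the gamma index. Ships a parametric digital head phantom
    generator so the full pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
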