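Package: fccstools
Title: Fluorescence Cross-Correlation Spectroscopy and Protein
    Degradation Kinetics for Live-Cell Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating in-cell protein-protein dissociation
    constants from dual-colour fluorescence (cross-)correlation
    spectroscopy, and for quantifying single-cell protein degradation
    kinetics from anaphase-aligned fluorescence trajectories. Provides a
    multi-tau correlator with a brute-force reference estimator,
    closed-form 3D free-diffusion correlation models with weighted
    nonlinear fitting, conversion of correlation amplitudes to absolute
    concentrations and dissociation constants via mass-action
    equilibrium, photobleaching correction, degradation-onset and
    maximum-speed detection, confocal line-profile extraction, and a
    seeded synthetic-data generator (Brownian-dynamics photon traces,
    model correlation curves, degradation trajectories, line-profile
    images) so every stage is verifiable against recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
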