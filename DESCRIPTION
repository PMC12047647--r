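Package: nibsim
Title: Desk-Scale Personalized Non-Invasive Brain Stimulation Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained modeling chain for non-invasive brain
    stimulation (NIBS) planning and virtual neuroimaging on synthetic
    volume-conductor head phantoms. The package generates multi-shell
    voxel phantoms with 10-10 electrode montages, maps diffusion tensors
    to clamped anisotropic conductivity tensors, solves the
    electroquasistatic Laplace equation with a finite-volume scheme to
    obtain per-electrode electric-field bases and reciprocity-based EEG
    lead fields, computes temporal-interference exposure metrics with
    Pareto multi-objective electrode/current optimization and current
    steering, simulates Jansen-Rit neural-mass networks with delayed
    long-range coupling and lambda*E stimulation coupling, projects the
    resulting source dynamics to virtual EEG, and analyzes dynamic
    functional connectivity states via sliding-window correlation,
    k-means clustering and PCA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
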