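Package: f19rad
Title: Repeatability of Radiomic Features in Fluorine-19 MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for assessing test-retest
    repeatability of radiomic features in fluorine-19 magnetic resonance
    imaging. Provides a seeded generator of phantom, in-vivo-like and
    pure-noise magnitude-MR acquisitions with Rician noise; slice-wise
    noise-floor estimation and threshold-based semi-automatic segmentation;
    a from-scratch radiomic feature engine (image filters, first-order,
    3D shape and five gray-level texture-matrix families); concordance
    correlation coefficient and normalized dynamic range stability scoring
    with Bland-Altman, intraclass correlation and Jensen-Shannon divergence
    diagnostics; and an orchestrated study pipeline with stable-feature
    intersection and threshold sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
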