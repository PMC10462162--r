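Package: fclong
Title: Longitudinal Functional Connectivity Analysis over Network Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for longitudinal resting-state functional connectivity
    (FC) analysis with a sphere-based brain parcellation grouped into
    functional networks. Builds bandpass-filtered Pearson FC matrices from
    4D fMRI volumes or region-of-interest timeseries, reduces edge-level FC
    to inter-network block averages, tests block-level longitudinal change
    with Bonferroni correction, predicts scan order from signed FC
    differences with regularized logistic regression and bootstrap learning
    curves, compares cross-sectional age groups, and correlates phenotypes
    with FC change. Includes a calibrated synthetic cohort generator so the
    whole pipeline is testable without access to restricted imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    signal,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
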