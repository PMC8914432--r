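Package: radresp
Title: Radiosensitivity Profiling and Tumor Control Modeling for Photon
    and Carbon-Ion Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the radioresponse of tumour cell-line panels
    across radiation qualities. Fits clonogenic survival curves with the
    repairable conditionally repairable (RCR) model, derives radiosensitivity
    metrics (SF2, SF3.5, D10, mean inactivation dose by closed form and by
    trapezoidal area under the curve, limiting slope D0), computes endpoint-wise
    relative biological effectiveness (RBE) for a test radiation quality against
    a photon reference, clusters cell-line panels into radiosensitivity cohorts
    from SF3.5, classifies cohorts from gene-expression profiles with F-test
    feature ranking and support-vector machines under repeated stratified
    cross-validation, and models tumour control probability (TCP) under
    fractionated schedules, including the dose differential ("underdosing")
    incurred when a fixed rather than a cell-line-specific RBE converts
    photon-equivalent (GyE) prescriptions to physical dose. Ships a 38-line
    head-and-neck squamous cell carcinoma (HNSCC) panel of surviving fractions
    and plating efficiencies, plus simulators for Poisson-noised clonogenic
    assays and group-structured expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
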