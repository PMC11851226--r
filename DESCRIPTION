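Package: lesionconn
Title: Lesion-Aware Resting-State fMRI Connectomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state functional-connectivity analysis in the
    presence of focal brain lesions. Builds combined tumor/resection masks,
    excludes lesioned atlas parcels, extracts mean regional BOLD time series,
    computes Fisher z-transformed correlation matrices and the scalar
    summaries tumor-to-extralesional (Tu-EL), extralesional (EL) and
    contralesional-hemisphere (conEL) connectivity, and relates them to
    cognitive scores through group-bound winsorization, partial correlation
    with covariates, Bonferroni correction and mixed repeated-measures
    analysis of covariance. Ships a fully deterministic synthetic-cohort
    generator with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    signal,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
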