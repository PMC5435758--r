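Package: calbold
Title: Graded-Hypercapnia Calibrated BOLD with a Dose-Wise CMRO2 Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint estimation of the calibrated-BOLD scaling parameter M and
    the dose-wise basal CMRO2 response to hypercapnia (kappa) from BOLD and
    cerebral blood flow responses measured at two or more end-tidal CO2
    levels, relaxing the classical iso-metabolic hypercapnia assumption.
    Includes the Davis-model forward equations and their inversion,
    bounded nonlinear least-squares fitting with an exact two-level oracle,
    boundary-aware group statistics with Wilcoxon signed-rank tests,
    dual-echo arterial spin labeling preprocessing (surround subtraction
    and averaging, two-echo R2* estimation, baseline detrending, block
    response and end-tidal level extraction, ROI averaging), a synthetic
    dual-echo ASL experiment generator with known ground truth for
    parameter-recovery validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
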