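Package: equiasym
Title: Movement Asymmetry and Pain-Scale Analysis for Induced Equine
    Orthopedic Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies equine hindlimb lameness from vertical marker
    displacement at trot (stride segmentation, side assignment, HDmin and
    PDmin minima differences, total asymmetry score relative to baseline)
    and links it to ordinal pain-scale assessments at rest: tie-corrected
    Kendall's coefficient of concordance for inter-observer reliability,
    Lasso regression with cross-validation to select scale items
    predicting asymmetry, and multiple correspondence analysis of item
    co-occurrence followed by a mixed-model regression of asymmetry on
    retained dimensions with AIC backward elimination.  A synthetic-data
    module generates gait trajectories and observer score tables with
    known ground truth so the full pipeline is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
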