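Package: cx43ep
Title: Connexin-43 Histomorphometry and In Silico Ventricular Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies connexin-43 (CX43), fibrosis and lipofuscin features
    from multi-channel ventricular immunofluorescence images (amount,
    expression level, spatial heterogeneity, lateralization, fibrosis and
    lipofuscin fractions), generates synthetic histology with known ground
    truth for validation, and maps the measured features onto tissue-level
    electrophysiology with a 2D monodomain simulator (O'Hara-Rudy epicardial
    and midmyocardial myocytes, MacCannell fibroblasts). Derived biomarkers
    include conduction velocity fields, APD90 maps, repolarization-gradient
    area and the S1-S2 vulnerability window, plus the cohort statistics used
    to relate histology to age (Spearman, Mann-Whitney, extreme-group splits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
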