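Package: adipoquant
Title: Dixon MRI Body-Composition Quantification for Cachexia Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automated whole-body MRI body-composition analysis for longitudinal
    cachexia monitoring. Simulates multi-echo Dixon acquisitions on labeled
    digital phantoms (mouse- and human-scale), decomposes echo series into
    water and fat maps (flexible three-point decomposition with two-candidate
    off-resonance resolution, and two-point in/opposed-phase decomposition),
    segments visceral and subcutaneous adipose tissue and lean tissue water
    with per-slice active contours, and turns label volumes into compartment
    volumes, caudocranial profiles, percent-change tables and cohort
    statistics (ANOVA with Bonferroni correction, t tests, Pearson
    correlation, Shapiro-Wilk normality).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
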