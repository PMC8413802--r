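Package: epiilca
Title: Latent Class Profiles of Pandemic-Related Experiences from the EPII
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Person-centered profiling of epidemic/pandemic-related
    experiences measured with the 92-item Epidemic-Pandemic Impacts
    Inventory (EPII). Provides EPII dichotomization, domain counts and
    psychosocial scale scoring with screening cutoffs (PSS, PHQ-9, GAD-7,
    PC-PTSD-5, Duke-UNC social support); base-rate and Spearman screening
    of candidate indicators; maximum-likelihood latent class analysis of
    dichotomous indicators via multi-start EM; a class-enumeration battery
    (BIC, sample-size-adjusted BIC, CAIC, AWE, Bayes factors, approximate
    correct-model probabilities, relative and univariate entropy,
    parametric bootstrap likelihood-ratio test); classification-error-
    corrected three-step comparisons of classes on continuous and
    categorical distal outcomes with Bonferroni-adjusted pairwise tests;
    and a synthetic survey generator parameterized by published class
    profiles so the whole pipeline is testable without respondent-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
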