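Package: irpheno
Title: Multi-Phenotype Health Screening from Plasma Infrared Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline for phenotyping blood plasma
    from Fourier-transform infrared (FTIR) absorbance spectra: water-background
    correction, spectral truncation/masking and L2 normalization; chained
    multilabel classification of co-occurring metabolic phenotypes
    (dyslipidemia, hypertension, prediabetes, type 2 diabetes, healthy) with
    exhaustive chain-order search; multilabel evaluation (exact match ratio,
    Hamming score, Hamming loss) against a stochastic chance benchmark;
    leakage-safe cross-validation and sample-set-independent validation;
    ridge-regression calibration of clinical analytes and anthropometrics from
    spectra; harmonized metabolic-syndrome risk-factor scoring and incident
    forecasting. Includes a Beer-Lambert synthetic two-visit cohort generator
    so the whole pipeline is testable without restricted clinical data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
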