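Package: fgrms
Title: Serum Proteome Profiling for Fetal Growth Restriction Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An affinity mass spectrometry analysis pipeline for screening
    pregnancies for fetal growth restriction (FGR) from maternal serum
    MALDI-ToF proteome profiles. Covers simulation of synthetic profile
    spectra with known ground truth, internal two-point recalibration of the
    m/z axis on apolipoprotein C-I and transthyretin calibrant signals,
    integration of five apolipoprotein C-II/C-III marker ion signals,
    formation of the assessment quotients A, B and C, Youden-index optimal
    cut-off training, single and dual cut-off cumulative scoring with a fixed
    discriminator, patient-level consolidation of replicate spectra, and
    diagnostic performance evaluation (confusion metrics, ROC/AUC, minimal
    sample size).
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
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mzR,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
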