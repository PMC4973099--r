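Package: diastolr
Title: Diastolic Dysfunction Grading and Synthetic Septic Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements two rule-based categorization schemes for left
    ventricular diastolic dysfunction from transthoracic echocardiography --
    the ASE 2009 multi-parameter scheme with explicit handling of discordant
    and insufficient measurement panels, and a simplified two-parameter
    scheme based on septal e' and E/e' -- together with a calibrated
    synthetic generator for septic-shock cohorts (latent four-grade mixture,
    Gaussian-copula log-normal echo parameters, correlated missingness
    driven by a shared image-quality factor, comorbidity and 28-day outcome
    models) and the downstream association analysis: multivariable logistic
    regression for 28-day mortality with variance inflation diagnostics,
    random-forest permutation variable importance, ICU-free days, and
    per-grade group comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
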