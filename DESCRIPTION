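Package: hippnorm
Title: Age-Conditional Normative Percentile Curves for Hippocampal Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative modelling of automated hippocampal volumetry. Provides
    head-size normalization of hippocampal volumes to a fixed reference
    intracranial volume, maximum-likelihood fitting of Gamma and Logistic
    age-conditional percentile models with constant dispersion, generation of
    age-by-level volume threshold tables, single-case percentile lookup and
    abnormality flagging against fitted or published norms, validation
    statistics (percentile-coverage calibration, Cohen's kappa, diagnostic
    accuracy metrics), cross-cohort standardized scores, and a synthetic
    cohort generator that emulates the statistical structure of multi-tool
    volumetric studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
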