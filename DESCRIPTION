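Package: twinwpps
Title: Within-Pair Proximity Scores for Multi-Omic Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how similar two co-twins are at the scale of a whole
    data domain (proteome, metabolome, epigenetic age acceleration, external
    exposome) using Gaussian-kernel within-pair proximity scores (WPPS)
    computed on an inertia-weighted principal-component distance. Provides
    domain preprocessing (missingness filtering, minimum-value imputation,
    inverse-normal rank transformation, feature standardization, PCA outlier
    screening, epigenetic-age-acceleration residuals, lifestyle discordance
    coding), cross-domain WPPS regressions with zygosity stratification and
    one-sided z-tests, an exposome-wide association study (ExWAS) of WPPS on
    lifestyle discordance with Benjamini-Hochberg false-discovery-rate
    control, sensitivity analyses for skewed scores, and an ACE-structured
    synthetic twin-cohort generator for validation without access-restricted
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
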