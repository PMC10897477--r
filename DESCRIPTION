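Package: triopgs
Title: Between- and Within-Family Factor Models for Psychiatric Polygenic
    Score Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the factorial structure of psychiatric
    comorbidity with polygenic scores in mother-father-child trios. Provides a
    synthetic trio generator with a bifactor genetic architecture, latent
    assortative mating and sex-specific participation selection; a trio
    structural-equation engine with meiosis-fixed 0.5 transmission paths and
    full-information Gaussian maximum likelihood; exploratory factor
    extraction with geomin and bi-factor geomin gradient-projection rotation;
    and confirmatory estimation of partner latent correlations and
    selection-induced latent means, with BIC-guided sequential model search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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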