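Package: tracermix
Title: Dual-Biotracer Bayesian Diet Estimation from Fatty Acids and Stable Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative diet estimation for predators from paired biotracer
    data: fatty-acid (FA) profiles and stable-isotope (SI) ratios. Provides
    preprocessing (delta notation, whisker averaging, FA normalization,
    calibration-coefficient transfer of prey into predator space, trophic
    discrimination handling), distance-based source distinguishability
    screening (PERMANOVA with pairwise comparisons, NMDS ordination) with
    automatic aggregation of indistinguishable prey, and a Bayesian mixing
    model with Dirichlet-distributed diet proportions, multiplicative process
    error, optional concentration dependence, adaptive MCMC and
    Gelman-Rubin/Geweke convergence diagnostics. Includes a synthetic-data
    generator emulating multi-species pinniped study designs so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    coda,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
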