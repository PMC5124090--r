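Package: ipmdemog
Title: Regional Integrated Population Models for Songbird Demography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian state-space integrated population models (IPMs) for
    regional time series of a short-lived migratory songbird. Joins an
    abundance-index likelihood with Cormack-Jolly-Seber mark-recapture,
    Mayfield-type daily nest survival and brood-size likelihoods to estimate
    annual adult survival, productivity components, a recruitment scaling
    factor and the latent female population. Includes a synthetic-data
    generator with region presets, per-MCMC-iteration correlations between
    population growth rates and demographic rates, simulated growth-rate
    surfaces over the survival-by-productivity space, and counterfactual
    trajectories in which one region's survival or productivity is
    substituted into another's.
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
    readr,
    rjags,
    coda,
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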