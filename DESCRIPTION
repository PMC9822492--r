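Package: corneocap
Title: Equivalent-Capillary Modelling of Nanoparticle Diffusion Through
    the Stratum Corneum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models transdermal nanoparticle transport by reducing the
    brick-and-mortar geometry of the stratum corneum (keratinocyte bricks in
    lipid-channel mortar) to a single equivalent capillary via the
    Kozeny-Carman hydraulic radius, simulating Brownian motion of finite-size
    particles in that capillary with reflecting walls and an absorbing outlet,
    and fitting the cumulative passage curves with a Hill-form saturation
    model to estimate effective diffusion coefficients. Includes a closed-form
    first-passage oracle, seeded reproducible parameter sweeps over particle
    diameter and fluid viscosity, and comparison tables against the
    Stokes-Einstein free-diffusion prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
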