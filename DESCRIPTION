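Package: recordage
Title: Stochastic Modelling of the Age of the World's Oldest Person
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of the age of the world's oldest living
    person as a Markov record process driven by an inhomogeneous Poisson
    process of births and gamma-Gompertz lifespans with time-dependent
    mortality level. Provides the exact record-age distribution and its
    transition kernel, closed-form stationary theory for the homogeneous
    model (record-age, peaks and reign-length densities), a closed-form
    gamma-Gompertz-Makeham survival integral via the Gauss hypergeometric
    function, maximum-likelihood fitting of the mortality trend to oldest
    person titleholder data with an adaptive-tolerance Nelder-Mead
    meta-optimizer, backtesting, prediction of future record-age densities,
    and a Monte-Carlo simulator of titleholder successions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
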