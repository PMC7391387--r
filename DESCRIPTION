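Package: hipfrax
Title: Hip Fracture Incidence Estimation and FRAX-Style Fracture
    Probability Modelling
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building a country-specific fracture risk model from
    a regional hip-fracture registry: eligibility filtering and
    deduplication of multi-source case reports, age- and sex-specific
    incidence with exact (Garwood) Poisson confidence intervals,
    ratio-based imputation of major osteoporotic fracture rates,
    closed-form integration of piecewise-constant fracture and mortality
    hazards into 10-year and remaining-lifetime fracture probabilities
    under competing risk of death, and demographic projection of fracture
    counts onto population pyramids. Includes a deterministic
    district-registry fixture reconstructed from published surveillance
    counts and a synthetic-registry generator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
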