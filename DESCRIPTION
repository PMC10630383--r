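Package: aquarisk
Title: Groundwater Quality Assessment and Probabilistic Human Health Risk Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete groundwater-quality and non-carcinogenic
    human-health-risk workflow used in hydrogeochemical surveys: charge-balance
    quality assurance of major-ion analyses, drinking- and irrigation-standard
    exceedance summaries and named classification schemes, deterministic and
    Monte Carlo (probabilistic) hazard-quotient and hazard-index assessment for
    nitrate and fluoride with the risk certainty level statistic, marginal
    distribution fitting with Anderson-Darling, Kolmogorov-Smirnov and
    chi-square goodness-of-fit diagnostics, contribution-to-variance sensitivity
    analysis, Piper and Gibbs hydrochemical classification, ionic-ratio
    diagnostics and simplified mineral saturation indices, varimax-rotated
    principal component analysis and Ward hierarchical clustering, plus a
    copula-based synthetic sample generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    fitdistrplus
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
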