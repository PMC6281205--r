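Package: timbersim
Title: Spatially Explicit Simulation of Legal and Illegal Logging Economics
Version: 0.1.0
Authors@R:
    person("Timbersim", "Developers", email = "timbersim@example.org",
           role = c("aut", "cre"))
Description: An annual-timestep, spatially explicit simulator of a tropical
    timber industry on a raster landscape: friction surfaces and least-cost
    transport accumulation, logging-center areas of influence, land-rent
    (stumpage) mapping, reduced-impact logging (RIL) versus conventional
    logging (CL) harvest rules, logging-center capacity dynamics, and
    endogenous unpaved-road expansion. Includes a seeded synthetic-landscape
    generator, built-in LEGAL/ILLEGAL scenario configurations, and a
    reporting stage for per-land-category accounting and scenario-comparison
    (leakage) statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
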