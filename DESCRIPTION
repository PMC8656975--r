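Package: carmap
Title: Bayesian Disease Mapping of Hospital Admissions in Small Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area spatial epidemiology of urgent hospital admissions at
    census-tract resolution. Computes indirectly standardized admission ratios
    (SAR), fits Bayesian spatial Poisson models with Besag-York-Mollie (BYM),
    intrinsic CAR and Leroux random-effect priors by Markov chain Monte Carlo
    to obtain smoothed relative risks (SRR), posterior exceedance probabilities
    and DIC/WAIC model comparison, fits a shared-component joint model for two
    sexes, and detects spatial clusters with global Moran's I and Anselin local
    Moran (LISA) permutation tests. Includes a synthetic census-tract generator
    emulating the stratified population and admission structure of a
    three-year urban study area, plus an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
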