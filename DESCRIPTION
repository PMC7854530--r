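Package: carenets
Title: Nursing-Home Ownership Networks, Market Concentration, and Care Deficiencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demarcates latent nursing-home ownership networks within hospital
    referral regions (HRRs) from Nursing Home Compare style open data using
    exact legal-name matching of registered-organization owners, bipartite
    facility-owner graphs, and Louvain community detection; derives
    super-organization and market-concentration measures (HHI, AHHI, delta-HHI,
    affiliation class, mean ownership-group size); and relates them to weighted
    care-deficiency counts via a Bayesian cross-classified hierarchical Poisson
    model with state, HRR and facility random intercepts, reporting prevalence
    ratios, highest posterior density intervals, MCMC p-values and intraclass
    correlation coefficients. Includes a synthetic-data generator with planted
    ground truth so every pipeline stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    generics,
    igraph,
    ggplot2,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
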