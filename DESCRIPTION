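Package: maskgap
Title: Small-Area Supply and Demand Estimation for Rationed Surgical Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates village-level supply of a rationed good (adult
    surgical masks sold through pharmacies under a per-person quota) from
    raw 10-minute pharmacy inventory traces, reallocates store-level
    customer counts to administrative polygons through Voronoi service
    areas and areal interpolation, and models the relative risk of supply
    against population-based expected counts with Bayesian hierarchical
    count models (Poisson and negative binomial, with and without
    Besag-York-Mollie spatial random effects). Includes a synthetic-data
    generator for the whole pipeline, model comparison via DIC and WAIC,
    predictive error summaries, variance inflation factors, and choropleth
    export of relative risks and exceedance probabilities Pr(RR < 1).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    deldir,
    sp,
    jsonlite,
    coda,
    ggplot2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
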