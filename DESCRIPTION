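Package: mninet
Title: Single-Sample Microbiome Association Networks with Fragility and
    Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Infers direct (partial-correlation) association networks from
    compositional microbiome abundance tables via sparse inverse-covariance
    estimation on centered log-ratio data, and extracts a microbiome network
    of individual (MNI) for every sample by leave-one-out interpolation of
    the population network. Provides network connectivity and fragility
    (random node-removal robustness) statistics, degree-matrix ordination,
    and mediation / moderated-mediation (conditional process) models linking
    a dichotomous exposure, per-sample network properties, and continuous
    outcome indices. Includes a synthetic-data generator with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    car,
    cluster,
    glmnet,
    igraph,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    biomformat,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
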