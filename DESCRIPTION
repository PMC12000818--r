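Package: gromm
Title: Dimension-Grouped Mixed Membership Models for Multivariate
    Categorical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits dimension-grouped mixed membership models (Gro-M3) to
    multivariate categorical data such as survey responses.  Items are
    partitioned into groups; a subject draws one realization of its latent
    extreme profile per group, shared by all items in the group, so the model
    interpolates between the latent class model (one group) and the grade of
    membership model (one group per item).  Provides seeded simulation from
    the generative process, Metropolis-Hastings-within-Gibbs and fully Gibbs
    (Beta/CRT augmented) posterior samplers with closed-form full
    conditionals, executable strict and generic identifiability checkers
    based on Khatri-Rao column ranks, posterior summaries (posterior-mode
    grouping, label-aligned parameter estimates, adjusted Rand index, RMSE),
    WAIC-based selection of the numbers of groups and profiles, and sample
    and model-based Cramer's V association diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
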