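Package: unusualness
Title: Leave-One-Society-Out Unusualness of Categorical Song Codings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how unusual a song is within its geographic region from
    categorical codings of musical style (e.g. the 37 Cantometric features).
    Unusualness is the log-likelihood of a song's feature states under regional
    state frequencies estimated with all songs of the focal society left out,
    so a society's own repertoire never makes its songs look typical. The same
    statistic applies to categorical societal traits (kinship and economic
    variables). The package builds the contact and isolation covariates used to
    explain unusualness (great-circle neighbour counts, patristic distance to
    the nearest sampled language on a phylogeny, leave-one-out society mean
    unusualness), fits Bayesian multilevel Gaussian regressions via JAGS with
    variance-partitioned marginal and conditional R-squared, Pareto-smoothed
    importance-sampling LOO, exact-refit LOO and k-fold cross-validation, and
    includes a Dirichlet-mixture simulator of regional song repertoires,
    geography, language trees and traits with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
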