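Package: patchnet
Title: Spatial Patch Networks from Animal Movement Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how relocation
    sampling frequency and landscape fragmentation affect the assessment of
    landscape connectivity with spatial networks. Generates fragmented
    resource landscapes from an exponential-variogram Gaussian random field,
    simulates foragers as continuous correlated biased random walks (with
    optional predator avoidance or territorial scent-marking), builds
    unweighted patch-level networks from full or subsampled trajectories,
    diagnoses scale-free and small-world topology against random-graph null
    ensembles, scores minimum-planar-graph and distance-threshold connectivity
    models with Cohen's kappa, and quantifies information loss (missed
    patches, missed links, spurious links) as trajectories are thinned.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
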