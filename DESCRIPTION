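Package: morphnet
Title: Individual Morphological Brain Networks from Gray-Matter MRI
Version: 0.1.0
Authors@R: person("Morphnet", "Developers", email = "morphnet@example.org",
    role = c("aut", "cre"))
Description: Constructs single-subject morphological brain networks from
    voxel-based-morphometry gray-matter volume maps. Regional intensity
    distributions are estimated by Gaussian kernel density estimation with
    Scott's-rule bandwidths; edges are the exponentiated negative symmetric
    Kullback-Leibler divergence (KLS) between regional densities. Includes
    sparsity-threshold binarization, small-world and efficiency graph metrics
    with degree-preserving (Maslov) null ensembles, betweenness-based hub
    mapping and profile similarity/uniqueness scores, one-way random-effects
    intraclass-correlation test-retest reliability of edges and metrics,
    covariate (age) correlation analysis with FDR control, a synthetic
    cohort generator for end-to-end validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
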