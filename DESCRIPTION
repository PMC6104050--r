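Package: cgalign
Title: Heterogeneous Network Alignment via Colored Graphlets
Version: 0.1.0
Authors@R:
    person("cgalign", "developers", email = "cgalign@example.org",
           role = c("aut", "cre"))
Description: Global pairwise alignment of node- and edge-colored (heterogeneous)
    networks. Provides colored-graphlet node signatures (NCGDV/ECGDV) built on
    2-5-node graphlet orbit counting, PCA plus cosine node similarities, a
    color-aware S3 edge-conservation measure, and heterogeneous versions of
    three alignment strategies: seed-and-extend (WAVE-style), simulated
    annealing (SANA-style), and a genetic search (MAGNA-style). Includes
    generators for geometric and scale-free benchmark networks with balanced
    random node colors and x%-rewired noisy counterparts with known true node
    mappings, plus a noise-sweep evaluation harness with node-correctness
    scoring and rank-frequency summaries.
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
    withr
Config/testthat/edition: 3
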