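Package: signedRoles
Title: Role-Based Embedding and Comparative Analysis of Signed Gene
    Regulatory Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural (role-based) embedding of signed gene regulatory
    networks. Genes are summarised by signed degrees, compared across
    multi-hop neighbourhoods with a log-ratio degree distance and dynamic
    time warping, assembled into a multilayer similarity graph, and
    embedded with Skip-Gram over biased random walks. Networks from
    several cell types or states share one embedding space, enabling
    identification of differentially topological genes and stability
    scoring of gene modules between states. Includes signed-network
    construction from count matrices via Spearman correlation, seeded
    synthetic network generators for benchmarking, and signed topology
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
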