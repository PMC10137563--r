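Package: ndfawm
Title: Estimating the Number of Communities in Weighted and Signed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of communities K in undirected weighted
    networks, including networks with negative edge weights and signed
    networks. Candidate partitions for k = 1..K0 are produced by nDFA
    spectral clustering (top-k eigendecomposition by eigenvalue magnitude,
    row normalization, k-means) and scored by a generalized weighted
    modularity that decomposes the adjacency matrix into its positive and
    negative parts; the estimate is the k maximizing the modularity curve.
    Also provides a simulator for the degree-corrected distribution-free
    model (DCDFM) with nine edge-weight distribution families (Bernoulli,
    binomial, Poisson, geometric, exponential, normal, Laplace, uniform,
    and signed), built-in simulation-study settings with accuracy-rate
    summaries, and readers/writers for TSV edge lists, GML, Pajek and CSV
    adjacency formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
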