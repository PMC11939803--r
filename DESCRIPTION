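Package: mcentropy
Title: Maximum-Entropy Markov Chains on Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-sample weighted gene regulatory networks as
    maximum-entropy Markov chains whose support is a fixed interaction
    topology and whose stationary distribution is the L1-normalised gene
    expression of the sample. Provides Markov chain entropy and per-gene
    Markov flow entropy, a DNA-methylation network index obtained by
    contrasting fits before and after removal of fully methylated genes,
    weighted PageRank ranking with k-means score clustering, triplet
    co-occurrence analysis for stable core- and bridge-gene extraction,
    and a synthetic-data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    methods,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
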