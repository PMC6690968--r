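Package: linkess
Title: Link Clustering Analysis of Essential Genes in Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates essential genes in protein-protein interaction networks
    into centrality-explained (k-dependent) and link-clustering-explained
    (w-dependent) subsets and quantifies their distinct structural signatures.
    Provides node and edge clustering measures (C, CXC, LCC, ECC and their
    node-level aggregates), binned essentiality correlations, degree-preserved
    network randomization and pruning curves of excess clustering,
    leave-one-out logistic classification of essential genes with MCC-optimal
    cutoffs, hypergeometric term-enrichment networks with shuffle z-tests and
    clique-bias statistics, Walktrap-based hierarchical community analysis of
    per-node link-density impact, contextual-essentiality broadness statistics
    over fitness screens, and a synthetic benchmark generator with planted
    hubs and modules for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
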