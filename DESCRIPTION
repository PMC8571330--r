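Package: fibrokit
Title: Meta-Analysis Toolkit for Pulmonary Fibrosis Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-agnostic toolkit for integrating differential expression
    results across pulmonary fibrosis transcriptomic datasets. Provides
    dataset benchmarking with star accreditation against group-level metric
    distributions, vote-counting consensus differential-expression calling
    within and across species (via one-to-one homology), miRNA-mRNA
    anticorrelation integration, query-centred two-shell protein-protein
    interaction networks with condition-specific deregulation labels, and
    co-expression subnetwork extraction from precomputed module data. A
    seeded synthetic-data generator with controlled ground truth makes every
    analysis testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
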