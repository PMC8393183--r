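Package: mesoconn
Title: Bottom-Up Transcriptome-to-Connectome Multilayer Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a brain 'mesoconnectome' from a genes-by-regions expression
    matrix: variance-based selection of variant genes by a derivative sweep,
    a Jensen-Shannon divergence gene co-expression network thresholded at the
    maximum betweenness-distribution entropy, leading-eigenvector gene
    communities with Erdos-Renyi null comparison, a community-layered multiplex
    network over brain regions with multilayer degree, PageRank, eigenvector
    centrality and k-core, and multilayer Louvain brain modules. Includes a
    synthetic expression generator with planted gene communities and region
    modules for parameter-recovery testing, and an end-to-end pipeline with a
    machine-readable run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
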