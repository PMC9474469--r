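Package: elsanet
Title: Time-Delayed Co-Occurrence Networks from Replicated Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extended local similarity analysis (eLSA) for replicated OTU
    time series: replicate-averaged trajectories are scored with a
    local-alignment dynamic program allowing a bounded time delay, edges are
    called by permutation significance, and per-treatment co-occurrence
    networks are compared through modularity, density, average path length
    and exclusive-edge counts. Includes a synthetic-data generator that
    emulates a multi-generation host-mediated selection experiment with
    planted associations for ground-truth recovery, plus the surrounding
    community statistics (rarefaction, Shannon diversity, Bray-Curtis
    distances, principal coordinates analysis, PERMANOVA, family-level
    aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
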