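Package: comorbnet
Title: Comorbidity Networks from ICD-10 Healthcare Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for building disease co-occurrence networks from
    longitudinal ICD-10 healthcare claims. Claims are aggregated into
    patient-year diagnosis sets, pairwise associations are tested with
    Spearman's rank correlation (optionally Benjamini-Hochberg adjusted),
    significant associations are assembled into an undirected weighted
    network with hub statistics and a reproducible force-directed layout,
    and yearly co-occurrence trends are screened for utilization disruptions
    and rebounds. A Gaussian-copula synthetic claims generator plants known
    prevalences, pairwise odds ratios, demographics and yearly utilization
    shocks so the whole pipeline is testable without access-restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    igraph,
    generics,
    withr,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
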