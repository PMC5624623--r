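Package: wardflow
Title: Network Analysis of Patient Flow Between Hospital Wards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing intra-hospital patient flow as a temporal
    weighted directed network. Builds ward-transfer networks over daily,
    weekly or monthly windows, computes node-level statistics (in/out-degree
    roles, an edge-weight variability score, path-based centrality),
    extracts the stable core sub-network and quantifies the flow it carries,
    reconstructs per-admission ward sequences, relates flow to daily
    emergency-department performance through lagged differential networks,
    and clusters daily flow snapshots by principal component analysis.
    Includes a discrete-event synthetic hospital generator with planted
    core structure, weekend modulation and lagged performance coupling for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    igraph,
    jsonlite,
    digest,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
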