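Package: psenet
Title: Process-Drug-Side-Effect Network Construction from Drug
    Perturbation Rank Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a tripartite biological-process / drug / side-effect
    (ABC) network from connectivity-map style per-instance gene rank
    profiles, GO-style gene sets, SIDER-style drug/side-effect frequency
    records and a DrugBank-style synonym table.  Enrichment of each gene
    set in each treatment instance is scored with an unweighted running-sum
    (Kolmogorov-Smirnov style) statistic, robust-standardized across
    instances with median/MAD t-scores, and thresholded into drug-process
    edges; side-effect relations are frequency-filtered and
    synonym-normalized; the two layers are merged over shared drugs and
    process/side-effect pairs are scored by drug co-occurrence (CD/TD),
    with permutation-derived significance thresholds per side-effect
    degree.  Includes a synthetic-scenario generator with planted ground
    truth so every stage is testable offline, and a simplified
    literature-evaluation harness based on normalized edit distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
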