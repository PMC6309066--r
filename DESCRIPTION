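Package: comorbnet
Title: Disease Comorbidity Networks from Case-Report Co-Occurrence Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines disease co-occurrence association rules from case-report
    transaction data (such as FDA Adverse Event Reporting System indication
    files) with a from-scratch FP-growth implementation, builds an
    undirected disease comorbidity network from the rules, detects network
    communities by the Girvan-Newman edge-betweenness algorithm with
    modularity-maximizing cuts, validates clusters against disease-ontology
    Resnik semantic similarity and shared gene/drug annotations using a
    node-label-shuffling permutation null with t-tests, and prioritizes
    diseases associated with a seed by random walk with restart. Includes a
    synthetic-data generator with planted cluster structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust,
    jsonlite
Config/testthat/edition: 3
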