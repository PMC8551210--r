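Package: mobflow
Title: Mobility-Network Disruption and Socioeconomic Segregation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the disruption and recovery of human-mobility
    networks under non-pharmaceutical interventions and to relate territorial
    disruption to pre-existing socioeconomic structure. Aggregates raw
    origin-destination flow records into 14-day weighted undirected networks
    over territorial units, computes global and nodal network efficiency with
    reciprocal-flow distances, derives per-territory lockdown and recovery
    indicators from relative variations in nodal efficiency, extracts the most
    and least affected territory classes from the indicator tails, tests their
    socioeconomic segregation (hierarchical-clustering purity, cross-validated
    classification, Kruskal-Wallis with Conover post-hoc tests), and fits
    quantile regressions of the indicators on standardized socioeconomic
    covariates with macroarea controls and wild-bootstrap robust standard
    errors. A seeded synthetic-scenario generator emulates the proprietary
    mobility and socioeconomic inputs so the full pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    pROC,
    randomForest,
    e1071,
    class,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
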