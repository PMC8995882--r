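Package: fflregnet
Title: Composite Feed-Forward-Loop Analysis of TF-miRNA-Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds typed transcription-factor/miRNA/gene regulatory networks
    from four categories of curated regulation pairs, performs an exhaustive
    census of role-coloured three-node motifs against a degree-preserving
    edge-switching null model, extracts the composite feed-forward-loop
    motif-specific sub-network, filters and clusters weighted protein-protein
    interaction graphs with MCODE-style module scoring, and screens drug-target
    tables for miRNA-drug association with a cumulative hypergeometric test.
    A synthetic-data module generates every pipeline input with known planted
    ground truth so the whole workflow is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
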