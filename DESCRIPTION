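Package: sonrank
Title: Ranking Essential Proteins by Integrating Subcellular Localization,
    Orthology and Network Centrality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks proteins in a protein-protein interaction (PPI) network by
    predicted essentiality using the SON score, a weighted linear combination
    of three normalized per-protein scores: an edge-clustering-coefficient
    network centrality (NNC), a subcellular-localization correlation score
    (NSL), and an orthology conservation score (NOS). Includes readers for
    two-column edge lists and annotation tables, the six classical baseline
    centralities, an evaluation suite (top-K histograms, precision-recall
    curves, jackknife curves, connectivity-stratified counts) and a synthetic
    benchmark generator with planted essentiality signal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
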