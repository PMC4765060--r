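Package: bigih
Title: Bilateral Gene Interaction Hierarchy Analysis of Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for bilateral (injured vs. mirror-side vs.
    naive) gene expression experiments. Implements MAS5-style detection
    calls from probe-pair discrimination scores, signed fold-change
    filtering with presence rules, the piecewise ipsilateral/contralateral
    fold-change ratio and its four-way partition of changed genes,
    genes-of-interest assembly with per-source overlap accounting,
    network-degree gene interaction hierarchy (GIH) tiering of genes of
    interest, right-tailed Fisher gene-set enrichment with rank-shift
    comparison, and delta-delta-Ct qPCR relative quantification. Includes
    a seeded synthetic-data generator (expression matrices, interaction
    networks with planted hubs, annotation sets) so the full pipeline is
    testable without external data, plus a bundled reference dataset from
    a unilateral controlled cortical impact study in rat.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
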