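Package: gametePIN
Title: Drug-Target Prioritization from Sperm-Egg Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses two-compartment (sperm/egg) protein-protein
    interaction networks to nominate putative drug targets. Combines
    per-channel interaction evidence with a noisy-OR score combiner, applies
    dual high-confidence filters (combined-score and physical/MI-score rules),
    assembles overlap, membrane and union networks, computes degree,
    betweenness and closeness centrality, shortest-path statistics and a
    log-log least-squares power-law fit of the degree distribution, classifies
    hub and bottleneck proteins by the half-of-maximum criterion, and joins
    targets against a bundled drug-association table. Includes a seeded
    synthetic-study generator with planted hubs so the whole pipeline is
    testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
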