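Package: ppitarget
Title: Patient-Specific Drug-Target Selection on Protein-Protein
    Interaction Networks via Gibbs Free-Energy Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects patient-specific protein-protein interaction (PPI)
    drug targets by overlaying normalized per-sample gene expression on a
    merged pathway-derived PPI network, scoring each protein's Gibbs
    free-energy contribution, and choosing the interaction between the
    most thermodynamically important protein (most negative Gibbs score)
    and its highest-expressed network neighbor. Per-sample target edges
    are aggregated across a cohort into a Pareto-ranked table. Includes
    readers for KEGG KGML pathway XML and plain edge lists, pathway
    merging, per-sample min-max expression normalization, auxiliary
    network statistics (degree-distribution entropy and betweenness
    centrality), and a seeded synthetic-cohort generator with planted
    target structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    graphics,
    withr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
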