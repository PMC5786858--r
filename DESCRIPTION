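Package: dismod
Title: Disease and Syndrome Module Detection in Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("dismod", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Partitions a weighted protein-protein interaction network into
    topological modules by weighted-modularity (Louvain/BGLL) community
    detection, identifies disease modules by hypergeometric enrichment of
    disease-associated gene sets under a joint p-value and relative-risk
    criterion, identifies syndrome modules from symptom-gene bipartite maps,
    and validates modules by overlaying drug-target and herbal-formula-target
    sets.  Includes over-representation analysis of annotation collections
    (GMT) with Bonferroni correction, a provenance ledger for merging
    disease-gene sources, a planted-partition synthetic-data generator so the
    whole pipeline is testable without database downloads, and a
    single-command pipeline driver with a flat config file.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
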