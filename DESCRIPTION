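Package: coocsig
Title: Mining Signature Pathways from Microbial Species Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-phenotype species co-occurrence networks from
    presence/absence profiles of shotgun-metagenome taxonomic data using an
    exact probabilistic (hypergeometric) pair test, analyses the networks at
    three granularity levels (global species sets, Leiden/CPM communities
    with a degree-quartile resolution heuristic, and top hub/betweenness
    species), maps species to the KEGG Orthologs they contribute via
    stratified functional profiles, performs hypergeometric pathway
    enrichment with Benjamini-Hochberg adjustment, and intersects
    disease-unique enriched pathways across independent datasets to report
    replicable signature pathways. Includes a synthetic-data generator with
    planted co-occurrence blocks and planted pathway signal for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
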