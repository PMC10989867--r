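Package: phylomarkers
Title: Congruence Ranking and Placement-Tendency Analysis of Phylogenomic Marker Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating phylogenomic marker-gene sets in deep archaeal
    phylogeny. Pools published marker catalogs into a nonredundant catalog with
    provenance, ranks markers by how well their single-gene trees recover the
    monophyly of well-established lineages, builds occupancy-filtered
    concatenated supermatrices with partition files, classifies each marker's
    placement tendency for a focal clade (sister to a TACK-like or an
    Asgard-like group) with multi-set Venn overlap statistics, and clusters
    genomes by UPGMA on eukaryotic-signature-protein presence-absence profiles.
    Includes a synthetic species-tree/gene-tree/alignment generator with
    controlled horizontal-transfer grafts and contaminant leaves so every stage
    is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
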