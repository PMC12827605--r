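Package: pathtracer
Title: Ancestral Gain, Loss and Transfer Histories of Carbon-Fixation Pathway Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the evolutionary history of multi-subunit pathway gene
    sets (the Wood-Ljungdahl and reductive glycine carbon-fixation pathways)
    across a bacterial phylum from protein homology-search hit tables, gene
    trees and genome annotation. Provides threshold-based homolog screening
    with metagenome-assembled-genome curation, boolean pathway-completeness
    calls from subunit presence, operon-style synteny cluster detection,
    gene-tree curation (long-branch pruning, bipartition monophyly,
    two-group splitting) with nestedness-based horizontal gene transfer
    classification, and Dollo/Fitch parsimony reconstruction of per-edge
    gain, loss and transfer events on a species tree. A fully seeded
    synthetic-data generator emits every input format with ground-truth
    logs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
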