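Package: coexclade
Title: Signed Weighted Gene Coexpression Networks with Clade Queries,
    Module Detection and Hub-Gene Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, weighted, TOM-based gene coexpression networks
    from an expression matrix: soft-threshold selection by scale-free fit,
    signed adjacency, topological overlap similarity and distance,
    average-linkage dendrograms with Newick export, dynamic-tree-cut module
    detection with eigengene-based module merging, module eigengene to tissue
    trait correlation, driver-gene coexpression clade queries with
    hypergeometric term enrichment (BH-FDR), and intramodular hub-gene
    identification by average distance ranking. Includes a synthetic
    block-modular expression generator with planted modules, tissue-linked
    eigengenes and annotation databases so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ape,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
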