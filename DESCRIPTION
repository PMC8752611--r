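Package: cciverse
Title: Downstream Analysis of Predicted Cell-Cell Communication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for the downstream analysis of predicted
    cell-cell communication. Standardizes ligand-receptor interaction tables
    (a custom schema or CellPhoneDB v2 output) into a unified model, summarizes
    communication per cluster pair and per gene (interaction counts, network
    edges, dot-plot data), annotates interaction pairs with functional terms
    from GMT gene-set collections, defines functionally similar interaction-pair
    modules by UMAP embedding and Ward hierarchical clustering with a one-sided
    permutation test for term specificity (module-ratio statistic), and compares
    communication across experimental conditions (count differences, unique
    couplets and interaction pairs, condition-specific significant terms).
    Includes a deterministic synthetic-fixture generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    cluster,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
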