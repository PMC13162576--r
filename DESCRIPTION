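Package: coabnet
Title: Weighted Protein Co-Abundance Network Analysis for Developmental
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for stage-resolved quantitative proteomics:
    log2 transformation and fast cyclic loess normalization of a protein by
    sample intensity matrix, per-protein one-way ANOVA across developmental
    stages with Benjamini-Hochberg false-discovery-rate control and Tukey HSD
    post hoc contrasts, principal component analysis with PERMANOVA
    validation of stage grouping, a weighted co-abundance network core
    (soft-threshold selection by scale-free topology fit, topological overlap,
    hierarchical module detection, module eigengenes, eigengene-based module
    merging, kME module membership, module-trait correlation with a
    permutation null, and hub-protein prioritization), over-representation
    analysis of module members against user-supplied annotation sets, and a
    seeded synthetic-data generator with planted modules, stage trends and
    trait couplings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
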