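Package: nutrinet
Title: Integrative Differential Expression and Co-Expression Network
    Analysis for Nutrigenomic Feeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for integrative nutrigenomic analysis of 2x2
    strain-by-diet feeding trials in fish, as used to study plant-protein
    tolerance in rainbow trout. Implements negative-binomial two-group
    differential expression over the four design contrasts, a
    signed-hybrid weighted gene co-expression network (soft threshold,
    topological overlap, module detection, eigengenes, module merging and
    module-trait correlation), hub / |kME + Cor| / top-DEG candidate-gene
    integration, Fisher's-exact functional enrichment, KEGG-style pathway
    perturbation counting, and nonparametric histopathology scoring
    (Kruskal-Wallis with Dunn's post-hoc test). A synthetic-data
    generator emulating the study design (two strains, two diets, two
    tissues, planted co-expression modules and traits) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
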