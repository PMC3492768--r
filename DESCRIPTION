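Package: honeypop
Title: Neutral Genetic Structure and Adaptive Phenotypic Divergence Along a
    Rainfall Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint analysis of microsatellite population structure and
    morphological divergence in songbird populations sampled along a rainfall
    gradient. Implements Weir-Cockerham F-statistics with jackknife
    confidence intervals, Hardy-Weinberg and linkage-disequilibrium
    permutation tests, assignment-index tests of sex-biased dispersal,
    isolation-by-distance Mantel tests on Rousset-linearized F_ST,
    P_ST-versus-F_ST comparison from one-way ANOVA variance components, and a
    condition-index scan that classifies the mode of selection on
    morphological traits. A stepping-stone genotype and phenotype simulator
    with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
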