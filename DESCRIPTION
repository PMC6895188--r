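Package: cerebrotype
Title: Multi-Level Ecomorphology of Cerebellar Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-level comparative analysis of brain (cerebellar)
    architecture against ecological predictors such as locomotor mode.
    Implements 3D landmark geometric morphometrics (generalized Procrustes
    superimposition, shape PCA, between-group PCA, thin-plate-spline warping
    and mean-shape deviation fields), phylogenetic comparative statistics
    (multivariate Blomberg's K, distance-based phylogenetic ANOVA and
    regression with residual-randomization permutation, distance-based
    convergence measures C1-C4), volumetric allometry (Pagel's lambda GLS
    lines, slope-homogeneity testing and Johnson-Neyman regions of
    significance), Purkinje-cell scattering statistics (Kruskal-Wallis with
    Dwass-Steel-Critchlow-Fligner post hoc tests and pattern partitioning),
    and downstream expression-matrix comparisons (filtering, clustering with
    multiscale-bootstrap AU support, hypergeometric GO enrichment). A
    synthetic-data generator reproduces the statistical structure of each
    data level so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    mclust
Config/testthat/edition: 3
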