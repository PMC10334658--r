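Package: microrewire
Title: Differential Co-Occurrence Network Rewiring for Multi-Study Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for case-control microbiome studies built
    around differential ("rewired") taxon co-occurrence networks. Reads,
    collapses, normalizes and merges multi-study taxon-by-sample feature
    tables on their shared taxa; compares alpha diversity (observed richness,
    Shannon, Gini-Simpson) and beta diversity (Bray-Curtis, PCoA, PERMANOVA,
    beta-dispersion) between groups; screens per-taxon differential abundance
    with Wilcoxon rank-sum tests under Benjamini-Hochberg FDR control;
    detects taxon modules with DBSCAN on abundance profiles; and builds
    per-condition Pearson co-occurrence networks whose significant edge sets
    are compared to classify gained, lost and changed-direction interactions,
    with per-node rewiring degree, Cytoscape-convention centralities and
    degree-based hub calls. Includes a logistic-normal/multinomial synthetic
    data generator with extractable ground truth (planted differential taxa,
    taxon modules and condition-specific correlation structure) for
    end-to-end validation, plus Cytoscape-compatible exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
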