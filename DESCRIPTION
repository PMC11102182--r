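Package: lipomix
Title: Integrated Transcriptomic and Lipidomic Analysis of Nitrogen-Starvation
    Lipid Remodeling in Oleaginous Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for studying lipid
    accumulation under nitrogen limitation in oleaginous yeasts such as
    Rhodotorula toruloides. Converts lipidomic peak intensities to absolute
    amounts (pmol per OD600 unit) by one-point internal-standard calibration,
    aggregates lipid classes and tracks the remodeling of the lipid pool from
    membrane phospholipids (PC, PE, PG, PI) to storage lipids (DAG, TAG);
    normalizes and row-scales RNA-seq count matrices, applies a twofold
    differential-expression rule, and clusters genes and samples
    hierarchically with PCA ordination; integrates the two omic layers through
    a lipid-by-gene Pearson correlation clustermap with TAG-sign gene
    labeling (P1/P2), per-pathway up/down and TAG-correlation fractionation,
    and pathway-map reaction coloring. A synthetic multi-omic generator with
    planted ground truth (expression clusters, lipid trajectories, pathway
    membership) makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
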