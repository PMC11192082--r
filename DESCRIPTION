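Package: fibroharmony
Title: Harmonization of Cardiac Fibroblast States Across Single-Cell Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing cardiac-fibroblast transcriptional states
    across single-cell RNA-seq datasets, diseases, and species. Provides
    k-nearest-neighbor majority-vote refinement of cluster labels on an
    integrated embedding, neighbor-purity matrices for judging batch mixing
    against biological state retention, random-forest projection of reference
    state labels with stratified cross-validation, marker detection with
    Bonferroni/fold-change filtering, Jaccard and Fisher's-exact matching of
    marker sets across datasets, binned-control gene-set module scores,
    permutation-normalized weighted-mean regulon activities, marker-weighted
    spatial spot scores with bivariate maps, partitioning of mixed
    cell/nucleus captures by the product of ribosomal and lncRNA module
    scores, and a seeded synthetic-data generator that plants populations,
    markers, batch effects, spot mixtures, and cell/nucleus mixtures so every
    stage is testable without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    ranger,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
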