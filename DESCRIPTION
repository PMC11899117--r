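Package: milkEpimap
Title: Peptide-Microarray Epitope Mapping and Tolerance Prediction for
    Cow's Milk Allergy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linear B-cell epitope mapping of the five major
    cow's-milk allergens with overlapping-peptide microarrays, and for
    predicting clinical tolerance from baseline serology and peptide
    binding. Implements tiling-peptide library design (20-mers, 3-residue
    offset), Z-score standardisation of spot fluorescence against PBS
    negative-control spots, positivity calling, binding intensity and
    diversity summaries, informative-epitope identification and region
    merging, allergic-versus-tolerant group comparisons, Pearson
    correlation average-linkage clustering, and gradient-boosted tree
    models of later tolerance. A synthetic cohort generator emulates a
    longitudinal milk-allergy study (visit-wise tolerance acquisition,
    dropout, serology, raw spot tables) so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    xgboost,
    pROC,
    ape,
    pheatmap,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, Epitope, Classification, Clustering, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
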