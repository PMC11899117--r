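#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' PeptideLibrary: an overlapping-peptide tiling of the milk allergens
#'
#' Ordered collection of tiled peptides across one or more allergen
#' proteins, together with the tiling parameters (window length and
#' offset in residues). Rows are in fixed protein display order
#' (αs1-casein, αs2-casein, β-casein, κ-casein, β-lactoglobulin) and
#' 1-based peptide index within each protein.
#'
#' @slot peptides [S4Vectors::DataFrame] with columns `protein` (ASCII
#'   allergen label), `index` (1-based ordinal within protein), `start`,
#'   `end` (1-based inclusive coordinates in the mature chain),
#'   `sequence` (amino-acid string) and `key` (feature identifier).
#' @slot window integer, peptide length in residues (20 on this array).
#' @slot offset integer, tiling offset in residues (3 on this array).
#' @export
setClass("PeptideLibrary",
  slots = c(peptides = "DataFrame", window = "integer", offset = "integer")
)

setValidity("PeptideLibrary", function(object) {
  pep <- object@peptides
  need <- c("protein", "index", "start", "end", "sequence", "key")
  if (!all(need %in% colnames(pep))) {
    return(paste("peptides must have columns:", paste(need, collapse = ", ")))
  }
  if (object@window < 1L || object@offset < 1L) {
    return("window and offset must be >= 1")
  }
  if (any(nchar(pep$sequence) != object@window)) {
    return("every peptide sequence must have length equal to the window")
  }
  for (p in unique(pep$protein)) {
    idx <- pep$index[pep$protein == p]
    if (!identical(as.integer(idx), seq_along(idx))) {
      return(sprintf("peptide indices for %s must be 1..N with no gaps", p))
    }
  }
  if (anyDuplicated(pep$key)) return("duplicate peptide keys")
  TRUE
})

#' BindingMatrix: standardized peptide-binding Z-scores for one isotype/visit
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the weighted
#' average Z-scores of one isotype (IgE or IgG4) at one study visit.
#' Rows are peptides in library order, columns are patients; the single
#' assay is named `"zscore"`. Missing cells (no usable replicate spot)
#' are `NA`. Isotype and visit live in `metadata()`.
#'
#' @export
setClass("BindingMatrix", contains = "SummarizedExperiment")

setValidity("BindingMatrix", function(object) {
  if (!"zscore" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'zscore' is required")
  }
  md <- S4Vectors::metadata(object)
  if (is.null(md$isotype) || !md$isotype %in% c("IgE", "IgG4")) {
    return("metadata()$isotype must be 'IgE' or 'IgG4'")
  }
  if (is.null(md$visit) || !md$visit %in% 1:6) {
    return("metadata()$visit must be an integer in 1..6")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("protein", "index") %in% colnames(rd))) {
    return("rowData must carry 'protein' and 'index'")
  }
  TRUE
})

#' ModelReport: fitted tolerance-prediction model with evaluation metrics
#'
#' @slot targetVisit integer, the visit whose accumulative-tolerance
#'   status the model predicts (2, 3 or 4).
#' @slot metrics named numeric: `train_auc`, `test_auc`, `f1`,
#'   `precision`, `recall`, `accuracy` (all in \[0, 1\]).
#' @slot importance data.frame with columns `feature` and `gain`
#'   (gain shares over the full model, summing to 1).
#' @slot params list of chosen hyperparameters.
#' @slot seed integer random seed used for split, folds and fit.
#' @slot model the fitted `xgb.Booster`.
#' @slot n named integer: training and test set sizes.
#' @export
setClass("ModelReport",
  slots = c(
    targetVisit = "integer",
    metrics = "numeric",
    importance = "data.frame",
    params = "list",
    seed = "integer",
    model = "ANY",
    n = "integer"
  )
)

setValidity("ModelReport", function(object) {
  need <- c("train_auc", "test_auc", "f1", "precision", "recall", "accuracy")
  if (!all(need %in% names(object@metrics))) {
    return(paste("metrics must include:", paste(need, collapse = ", ")))
  }
  m <- object@metrics[need]
  if (any(!is.na(m) & (m < 0 | m > 1))) return("metrics must lie in [0, 1]")
  if (any(object@importance$gain < 0)) return("importance gains must be non-negative")
  TRUE
})
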