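#' Pearson correlation distance between two binding profiles
#'
#' `d = 1 - r`, with `r` the Pearson correlation computed over
#' pairwise-complete positions. Identical profiles have distance 0,
#' exactly anti-correlated profiles distance 2.
#'
#' @param x,y numeric Z-score vectors of equal length.
#' @return non-negative distance in \[0, 2\].
#' @export
correlationDistance <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need >= 3 pairwise-complete positions")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("constant profile: zero variance after pairwise-complete filtering")
  }
  1 - stats::cor(x[ok], y[ok])
}

#' Pairwise correlation-distance matrix over patients
#'
#' @param bm a [BindingMatrix-class] (patients in columns). Patients
#'   with fewer than `minUsable` of their cells non-missing are dropped
#'   with a warning before distances are computed.
#' @param minUsable minimum usable-cell fraction per patient.
#' @return a [stats::dist] over the retained patients.
#' @export
bindingDistance <- function(bm, minUsable = 0.5) {
  z <- zscores(bm)
  usable <- colMeans(!is.na(z))
  drop <- colnames(z)[usable < minUsable]
  if (length(drop)) {
    warning("excluding ", length(drop), " patient(s) with < ",
            round(100 * minUsable), "% usable cells: ",
            paste(drop, collapse = ", "))
    z <- z[, usable >= minUsable, drop = FALSE]
  }
  if (ncol(z) < 2L) stop("need >= 2 patients to cluster")
  r <- stats::cor(z, use = "pairwise.complete.obs")
  if (anyNA(r)) stop("constant profile: undefined correlation for some patient pair")
  stats::as.dist(1 - r)
}

#' Average-linkage (UPGMA) clustering of patient binding profiles
#'
#' Hierarchical clustering of patients on the Pearson correlation
#' distance with average linkage — the method used to group patient
#' recognition patterns in the heatmaps. Merge heights are
#' non-decreasing (UPGMA on a metric produced from correlations) and
#' the result is invariant to patient input order up to leaf rotation.
#'
#' @inheritParams bindingDistance
#' @return an [stats::hclust] object (convert with [ape::as.phylo] for
#'   newick export).
#' @export
averageLinkageCluster <- function(bm, minUsable = 0.5) {
  stats::hclust(bindingDistance(bm, minUsable = minUsable), method = "average")
}

#' Render heatmap, TileMap and dendrogram artifacts
#'
#' Writes the figure-style outputs for one isotype × visit: a patient ×
#' peptide heatmap (patients ordered by the dendrogram, peptides in
#' library order, diverging colour scale on Z clipped to
#' `zlim`), a per-peptide TileMap table marking informative peptides,
#' the plotted Z-scores as TSV (bit-identical across runs), and the
#' dendrogram in newick format.
#'
#' @param bm a [BindingMatrix-class].
#' @param clust [stats::hclust] from [averageLinkageCluster()] (computed
#'   if `NULL`).
#' @param informative output of [informativePeptides()] (may be empty).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param zlim colour-scale bounds; values outside are clipped in the
#'   image only, never in the TSV.
#' @return named character vector of the files written, invisibly.
#' @export
renderOutputs <- function(bm, clust = NULL, informative = NULL,
                          dir = ".", prefix = NULL, zlim = c(-3, 10)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) {
    prefix <- sprintf("%s_visit%d", arrayIsotype(bm), arrayVisit(bm))
  }
  if (is.null(clust)) clust <- averageLinkageCluster(bm)
  z <- zscores(bm)[, clust$labels, drop = FALSE]

  tsv <- file.path(dir, paste0(prefix, "_zscores.tsv"))
  df <- data.frame(key = rownames(z), z, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  nwk <- file.path(dir, paste0(prefix, "_dendrogram.nwk"))
  ape::write.tree(ape::as.phylo(clust), file = nwk)

  tile <- file.path(dir, paste0(prefix, "_tilemap.tsv"))
  marked <- if (is.null(informative) || nrow(informative) == 0L) {
    character(0)
  } else informative$key
  tiles <- data.frame(key = rownames(z),
                      protein = SummarizedExperiment::rowData(bm)$protein,
                      index = SummarizedExperiment::rowData(bm)$index,
                      informative = rownames(z) %in% marked)
  utils::write.table(tiles, tile, sep = "\t", quote = FALSE, row.names = FALSE)

  png <- file.path(dir, paste0(prefix, "_heatmap.png"))
  zc <- pmin(pmax(z, zlim[1L]), zlim[2L])
  zc[is.na(zc)] <- 0
  breaks <- seq(zlim[1L], zlim[2L], length.out = 101L)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100L)
  pheatmap::pheatmap(t(zc), cluster_rows = clust, cluster_cols = FALSE,
                     color = pal, breaks = breaks, show_colnames = FALSE,
                     filename = png, silent = TRUE)
  invisible(c(zscores = tsv, newick = nwk, tilemap = tile, heatmap = png))
}
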