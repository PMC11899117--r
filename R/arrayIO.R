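#' Read a raw microarray spot table
#'
#' Reads per-spot fluorescence records in either of two dialects:
#'
#' * `"csv"`: a long table with columns `patient_id`, `visit`,
#'   `isotype`, `feature_id`, `intensity` and optionally `replicate`
#'   and `flag` (`ok`/`bad`). One file may hold many arrays.
#' * `"gpr"`: a GenePix results file (ATF header block followed by a
#'   tab-separated spot table). A GPR file is a single physical array,
#'   so `patient_id`, `visit` and `isotype` must be supplied. `ID` (or
#'   `Name`) maps to `feature_id`, the background-subtracted intensity
#'   column (default `"F532 Median - B532"`) maps to `intensity`, and
#'   negative `Flags` map to `flag = "bad"`.
#'
#' Replicate numbers are (re)assigned in file order within each
#' array × feature, matching the duplicate-printing layout (each
#' peptide printed twice; PBS negative-control spots interspersed with
#' feature id `"PBS"`). Quality findings — spots flagged bad, peptides
#' without exactly 2 usable replicates, feature ids absent from a
#' supplied library — are collected in a QC report retrievable with
#' [qcReport()]; they do not stop the read.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"gpr"`.
#' @param patient_id,visit,isotype array annotation, required for
#'   `"gpr"` (ignored for `"csv"`, which carries them as columns).
#' @param intensityColumn GPR column holding the background-subtracted
#'   signal.
#' @param library optional [PeptideLibrary-class] used to flag unknown
#'   feature ids in the QC report.
#' @return data.frame of spot records (columns `patient_id`, `visit`,
#'   `isotype`, `feature_id`, `replicate`, `intensity`, `flag`) with a
#'   `"qc"` attribute.
#' @export
readSpotTable <- function(path, dialect = c("csv", "gpr"),
                          patient_id = NULL, visit = NULL, isotype = NULL,
                          intensityColumn = "F532 Median - B532",
                          library = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  spots <- if (dialect == "csv") {
    .readSpotCSV(path)
  } else {
    .readSpotGPR(path, patient_id, visit, isotype, intensityColumn)
  }
  if (nrow(spots) == 0L) stop("no records in ", path)
  .annotateSpots(spots, library)
}

.readSpotCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "visit", "isotype", "feature_id", "intensity")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$flag)) tab$flag <- rep("ok", nrow(tab))
  tab$flag <- ifelse(tab$flag %in% c("bad", "BAD"), "bad", "ok")
  tab[c(need, "flag")]
}

.readSpotGPR <- function(path, patient_id, visit, isotype, intensityColumn) {
  if (is.null(patient_id) || is.null(visit) || is.null(isotype)) {
    stop("gpr dialect needs patient_id, visit and isotype (one array per file)")
  }
  lines <- readLines(path, n = 2L)
  if (!grepl("^ATF", lines[1L])) stop("not an ATF/GPR file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[2L]), "[[:space:]]+")[[1L]])
  tab <- utils::read.delim(path, skip = 2L + hdr[1L], check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  idcol <- intersect(c("ID", "Name"), colnames(tab))[1L]
  if (is.na(idcol)) stop("missing required column(s): ID/Name")
  if (!intensityColumn %in% colnames(tab)) {
    stop("missing required column(s): ", intensityColumn)
  }
  flag <- if ("Flags" %in% colnames(tab)) {
    ifelse(tab$Flags < 0, "bad", "ok")
  } else "ok"
  data.frame(
    patient_id = as.character(patient_id),
    visit = as.integer(visit),
    isotype = as.character(isotype),
    feature_id = as.character(tab[[idcol]]),
    intensity = as.numeric(tab[[intensityColumn]]),
    flag = flag,
    stringsAsFactors = FALSE
  )
}

# Assign replicate numbers in file order and build the QC report.
.annotateSpots <- function(spots, library = NULL) {
  arr <- paste(spots$patient_id, spots$visit, spots$isotype, spots$feature_id, sep = "\r")
  spots$replicate <- stats::ave(seq_len(nrow(spots)), arr, FUN = seq_along)
  spots <- spots[c("patient_id", "visit", "isotype", "feature_id",
                   "replicate", "intensity", "flag")]
  qc <- character(0)
  nbad <- sum(spots$flag == "bad")
  if (nbad > 0L) {
    qc <- c(qc, sprintf("%d spot(s) flagged bad and excluded from averaging", nbad))
  }
  pep <- spots[spots$feature_id != "PBS", ]
  ok_n <- tapply(pep$flag == "ok", paste(pep$patient_id, pep$visit, pep$isotype,
                                         pep$feature_id, sep = "\r"), sum)
  odd <- names(ok_n)[ok_n != 2L]
  if (length(odd)) {
    qc <- c(qc, sprintf("%d peptide feature(s) without exactly 2 usable replicates",
                        length(odd)))
  }
  if (!is.null(library)) {
    unknown <- setdiff(unique(pep$feature_id), peptideKeys(library))
    if (length(unknown)) {
      qc <- c(qc, paste("unknown feature id(s):", paste(unknown, collapse = ", ")))
    }
  }
  attr(spots, "qc") <- qc
  spots
}

#' QC report of a spot table
#' @param x object returned by [readSpotTable()]
#' @return character vector of QC findings (empty when clean)
#' @export
qcReport <- function(x) {
  qc <- attr(x, "qc")
  if (is.null(qc)) character(0) else qc
}

#' Fit the negative-control (PBS) distribution of one array
#'
#' Summarises the ok-flagged PBS spot intensities of a single array as a
#' location and scale against which peptide spots are standardized. The
#' default is the mean and the population standard deviation (divisor
#' `n`, not `n - 1`); `robust = TRUE` switches to median and MAD.
#'
#' @param spots spot records of one array, or a numeric vector of PBS
#'   intensities.
#' @param robust use median/MAD instead of mean/SD.
#' @return list with elements `location`, `scale`, `n` (class
#'   `"ControlDistribution"`).
#' @export
fitControls <- function(spots, robust = FALSE) {
  x <- if (is.numeric(spots)) {
    spots
  } else {
    spots$intensity[spots$feature_id == "PBS" & spots$flag == "ok"]
  }
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("insufficient controls: need >= 2 usable PBS spots")
  if (robust) {
    loc <- stats::median(x)
    sc <- stats::mad(x)
  } else {
    loc <- mean(x)
    sc <- sqrt(mean((x - loc)^2))
  }
  if (sc <= 0) stop("degenerate controls: zero spread among PBS spots")
  structure(list(location = loc, scale = sc, n = length(x)),
            class = "ControlDistribution")
}

#' Weighted average Z-scores of one array
#'
#' Standardizes every replicate spot against the array's PBS control
#' distribution, `z = (intensity - location) / scale`, then averages
#' replicates per peptide with quality weights (1 for `ok`, 0 for
#' `bad`). A peptide whose replicates are all flagged bad gets `NA`.
#'
#' @param spots spot records of a single array (one patient × visit ×
#'   isotype); PBS rows are ignored here.
#' @param controls a `ControlDistribution` from [fitControls()].
#' @param keys peptide keys defining the output order (defaults to the
#'   peptide features present, in file order).
#' @return named numeric vector of weighted average Z-scores.
#' @export
computeZscores <- function(spots, controls, keys = NULL) {
  stopifnot(inherits(controls, "ControlDistribution"))
  pep <- spots[spots$feature_id != "PBS", , drop = FALSE]
  if (is.null(keys)) keys <- unique(pep$feature_id)
  z <- (pep$intensity - controls$location) / controls$scale
  w <- as.numeric(pep$flag == "ok")
  f <- factor(pep$feature_id, levels = keys)
  keep <- !is.na(f)
  num <- rowsum(z[keep] * w[keep], f[keep])[, 1L]
  den <- rowsum(w[keep], f[keep])[, 1L]
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- keys
  out
}

#' Positivity call for a weighted average Z-score
#'
#' A peptide is called positive when its weighted average Z-score
#' exceeds 3 — strictly: `z = 3` is negative. Missing Z-scores yield a
#' missing call (`NA`), which is excluded from diversity counts and
#' recognition fractions downstream.
#'
#' @param z numeric vector of Z-scores.
#' @param threshold positivity cut-off (default 3).
#' @return logical vector (`NA` where `z` is missing).
#' @examples
#' callPositive(c(2.9, 3, 3.000001, NA))
#' @export
callPositive <- function(z, threshold = 3) {
  ifelse(is.na(z), NA, z > threshold)
}

#' Assemble a BindingMatrix from spot records
#'
#' Normalizes every array (patient) of one isotype × visit against its
#' own PBS spots and assembles the peptides × patients Z-score matrix in
#' library order.
#'
#' @param spots spot records (see [readSpotTable()]); may span several
#'   isotypes/visits, the relevant slice is selected.
#' @param library a [PeptideLibrary-class] fixing the row order.
#' @param isotype `"IgE"` or `"IgG4"`.
#' @param visit study visit, 1..6.
#' @param robustControls use median/MAD PBS summaries (see
#'   [fitControls()]).
#' @return a [BindingMatrix-class]
#' @export
buildBindingMatrix <- function(spots, library, isotype, visit,
                               robustControls = FALSE) {
  sel <- spots$isotype == isotype & spots$visit == visit
  spots <- spots[sel, , drop = FALSE]
  if (nrow(spots) == 0L) stop("no spots for ", isotype, " at visit ", visit)
  keys <- peptideKeys(library)
  per_patient <- split(spots, spots$patient_id)
  z <- vapply(per_patient, function(s) {
    ctl <- fitControls(s, robust = robustControls)
    computeZscores(s, ctl, keys = keys)
  }, numeric(length(keys)))
  BindingMatrix(z, library, isotype = isotype, visit = visit)
}

#' Construct a BindingMatrix from a Z-score matrix
#'
#' @param z numeric matrix, peptides (library order) × patients.
#' @param library the [PeptideLibrary-class] the rows follow.
#' @param isotype `"IgE"` or `"IgG4"`.
#' @param visit study visit, 1..6.
#' @return a [BindingMatrix-class]
#' @export
BindingMatrix <- function(z, library, isotype, visit) {
  z <- as.matrix(z)
  keys <- peptideKeys(library)
  if (nrow(z) != length(keys)) {
    stop("matrix has ", nrow(z), " rows but the library has ", length(keys),
         " peptides")
  }
  rownames(z) <- keys
  pep <- peptides(library)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(zscore = z),
    rowData = S4Vectors::DataFrame(protein = pep$protein, index = pep$index,
                                   start = pep$start, end = pep$end,
                                   row.names = keys),
    metadata = list(isotype = isotype, visit = as.integer(visit))
  )
  methods::new("BindingMatrix", se)
}

#' @describeIn BindingMatrix-class the Z-score assay (peptides × patients)
#' @param x,object a `BindingMatrix`
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' @rdname BindingMatrix-class
#' @export
setMethod("zscores", "BindingMatrix", function(x) {
  SummarizedExperiment::assay(x, "zscore")
})

#' @describeIn BindingMatrix-class isotype of the arrays (`"IgE"`/`"IgG4"`)
#' @export
setGeneric("arrayIsotype", function(x) standardGeneric("arrayIsotype"))

#' @rdname BindingMatrix-class
#' @export
setMethod("arrayIsotype", "BindingMatrix", function(x) S4Vectors::metadata(x)$isotype)

#' @describeIn BindingMatrix-class study visit of the arrays (1..6)
#' @export
setGeneric("arrayVisit", function(x) standardGeneric("arrayVisit"))

#' @rdname BindingMatrix-class
#' @export
setMethod("arrayVisit", "BindingMatrix", function(x) S4Vectors::metadata(x)$visit)

setMethod("show", "BindingMatrix", function(object) {
  z <- zscores(object)
  cat(sprintf("BindingMatrix: %s, visit %d — %d peptides x %d patients\n",
              arrayIsotype(object), arrayVisit(object), nrow(z), ncol(z)))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(z)),
              100 * mean(is.na(z))))
})

#' Write a BindingMatrix as TSV (patients × peptides)
#'
#' @param bm a [BindingMatrix-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeBindingTSV <- function(bm, path) {
  m <- t(zscores(bm))
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
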