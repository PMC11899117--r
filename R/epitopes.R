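#' Per-protein binding intensity and diversity
#'
#' Summarises a [BindingMatrix-class] into the two study variables used
#' throughout the analysis: binding *intensity*, the mean weighted
#' average Z-score over a protein's peptides, and *diversity*, the
#' number of positive peptides (Z-score > 3). Missing cells are
#' excluded from both; a patient with no usable cell for a protein gets
#' `NA` for both measures.
#'
#' @param bm a [BindingMatrix-class].
#' @param threshold positivity cut-off for the diversity count.
#' @return data.frame: `patient_id`, `visit`, `isotype`, `protein`,
#'   `intensity`, `diversity`, `n_peptides`, `n_missing`.
#' @export
summarizeProtein <- function(bm, threshold = 3) {
  z <- zscores(bm)
  prot <- SummarizedExperiment::rowData(bm)$protein
  out <- do.call(rbind, lapply(unique(prot), function(p) {
    zp <- z[prot == p, , drop = FALSE]
    n_ok <- colSums(!is.na(zp))
    data.frame(
      patient_id = colnames(z),
      visit = arrayVisit(bm),
      isotype = arrayIsotype(bm),
      protein = p,
      intensity = ifelse(n_ok > 0, colMeans(zp, na.rm = TRUE), NA_real_),
      diversity = ifelse(n_ok > 0,
                         colSums(callPositive(zp, threshold), na.rm = TRUE),
                         NA_integer_),
      n_peptides = nrow(zp),
      n_missing = nrow(zp) - n_ok,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  out
}

.allergicAt <- function(labels, visit) {
  lab <- labels[labels$visit == visit & labels$status == "allergic", , drop = FALSE]
  unique(lab$patient_id)
}

#' Informative peptides at one visit
#'
#' A peptide is *informative* at a visit when it is recognized
#' (positive, Z-score > 3) by more than 75% of the allergic patients at
#' that visit — strictly more: a recognition fraction of exactly 0.75
#' does not qualify. Allergic patients with a missing call for a
#' peptide are excluded from that peptide's denominator.
#'
#' @param bm a [BindingMatrix-class] for the visit.
#' @param labels data.frame with columns `patient_id`, `visit`,
#'   `status` (`allergic`/`tolerant`/`lost`).
#' @param visit visit to evaluate (defaults to the matrix's visit).
#' @param threshold recognition-fraction cut-off (default 0.75,
#'   exceeded strictly).
#' @param zThreshold positivity cut-off on the Z-score.
#' @return data.frame: `visit`, `isotype`, `key`, `protein`, `index`,
#'   `fraction`, `n_allergic` — one row per informative peptide, in
#'   library order.
#' @export
informativePeptides <- function(bm, labels, visit = arrayVisit(bm),
                                threshold = 0.75, zThreshold = 3) {
  allergic <- intersect(colnames(zscores(bm)), .allergicAt(labels, visit))
  if (length(allergic) == 0L) {
    stop("no reference group: zero allergic patients at visit ", visit)
  }
  calls <- callPositive(zscores(bm)[, allergic, drop = FALSE], zThreshold)
  n_eval <- rowSums(!is.na(calls))
  frac <- ifelse(n_eval > 0, rowSums(calls, na.rm = TRUE) / n_eval, NA_real_)
  rd <- SummarizedExperiment::rowData(bm)
  keep <- which(!is.na(frac) & frac > threshold)
  data.frame(
    visit = rep(as.integer(visit), length(keep)),
    isotype = rep(arrayIsotype(bm), length(keep)),
    key = rownames(calls)[keep],
    protein = rd$protein[keep],
    index = rd$index[keep],
    fraction = frac[keep],
    n_allergic = n_eval[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Merge contiguous informative peptides into named regions
#'
#' Runs of consecutive peptide indices within one protein collapse into
#' a single epitope region named by [regionName()] (e.g. `"κ-cas
#' 29–31"`); isolated peptides stay singletons. The reported fraction
#' is the minimum over member peptides (every member exceeds the
#' informativeness threshold by construction).
#'
#' @param informative output of [informativePeptides()] for a single
#'   visit × isotype.
#' @param library the [PeptideLibrary-class] (for index validation).
#' @return data.frame: `visit`, `isotype`, `region`, `protein`,
#'   `first_index`, `last_index`, `n_peptides`, `min_fraction`.
#' @export
mergeContiguous <- function(informative, library) {
  cols <- c("visit", "isotype", "region", "protein", "first_index",
            "last_index", "n_peptides", "min_fraction")
  if (nrow(informative) == 0L) {
    out <- data.frame(visit = integer(0), isotype = character(0),
                      region = character(0), protein = character(0),
                      first_index = integer(0), last_index = integer(0),
                      n_peptides = integer(0), min_fraction = numeric(0),
                      stringsAsFactors = FALSE)
    return(out[cols])
  }
  stopifnot(length(unique(informative$visit)) == 1L,
            length(unique(informative$isotype)) == 1L)
  out <- do.call(rbind, lapply(split(informative, informative$protein), function(d) {
    d <- d[order(d$index), , drop = FALSE]
    run <- cumsum(c(1L, diff(d$index) != 1L))
    do.call(rbind, lapply(split(d, run), function(r) {
      data.frame(
        visit = r$visit[1L],
        isotype = r$isotype[1L],
        region = regionName(r$protein[1L], min(r$index), max(r$index),
                            library = library),
        protein = r$protein[1L],
        first_index = min(r$index),
        last_index = max(r$index),
        n_peptides = nrow(r),
        min_fraction = min(r$fraction),
        stringsAsFactors = FALSE
      )
    }))
  }))
  out <- out[order(match(out$protein, .PROTEIN_ORDER), out$first_index), , drop = FALSE]
  rownames(out) <- NULL
  out[cols]
}

#' Epitopes informative at every supplied visit
#'
#' Intersects per-visit informative peptide sets (same isotype) and
#' merges the peptides informative at *all* visits into named regions —
#' the "recognized at all time points" epitopes.
#'
#' @param perVisit list of [informativePeptides()] outputs, one per
#'   visit (at least two).
#' @param library the [PeptideLibrary-class].
#' @return region data.frame as from [mergeContiguous()] (the `visit`
#'   column is `NA`: the regions span visits).
#' @export
persistentEpitopes <- function(perVisit, library) {
  stopifnot(length(perVisit) >= 2L)
  keys <- Reduce(intersect, lapply(perVisit, `[[`, "key"))
  first <- perVisit[[1L]]
  sel <- first[first$key %in% keys, , drop = FALSE]
  # conservative fraction: minimum across visits for each surviving peptide
  if (nrow(sel)) {
    for (d in perVisit[-1L]) {
      m <- match(sel$key, d$key)
      sel$fraction <- pmin(sel$fraction, d$fraction[m])
    }
  }
  out <- mergeContiguous(sel, library)
  out$visit <- NA_integer_
  out
}

#' Allergic-versus-tolerant comparisons at one visit
#'
#' For each protein × measure (intensity, diversity) of one isotype's
#' summaries, tests allergic against tolerant patients with a
#' two-sided Mann–Whitney (Wilcoxon rank-sum) test and adjusts the
#' family of p-values at that visit by Benjamini–Hochberg. At the
#' baseline visit every patient is still allergic, so groups are formed
#' by the 6-month outcome (accumulative tolerance status at
#' `baselineOutcomeVisit`).
#'
#' @param summaries output of [summarizeProtein()] (one isotype ×
#'   visit; rbind several isotypes to adjust across the joint family).
#' @param labels status table (`patient_id`, `visit`, `status`).
#' @param visit visit to compare.
#' @param baselineOutcomeVisit visit whose status classifies patients
#'   when `visit == 1` (default 2, the 6-month visit).
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame: `visit`, `isotype`, `protein`, `measure`,
#'   `n_allergic`, `n_tolerant`, `direction` (+1 when allergic >
#'   tolerant in medians), `p`, `q`, `significant`. Rows with an empty
#'   group are marked not evaluable (`NA` statistics).
#' @export
compareGroups <- function(summaries, labels, visit,
                          baselineOutcomeVisit = 2L, alpha = 0.05) {
  group_visit <- if (visit == 1L) baselineOutcomeVisit else visit
  lab <- labels[labels$visit == group_visit &
                  labels$status %in% c("allergic", "tolerant"), , drop = FALSE]
  status <- stats::setNames(lab$status, lab$patient_id)
  dat <- summaries[summaries$visit == visit, , drop = FALSE]
  dat$group <- status[dat$patient_id]
  dat <- dat[!is.na(dat$group), , drop = FALSE]

  grid <- expand.grid(protein = unique(dat$protein),
                      isotype = unique(dat$isotype),
                      measure = c("intensity", "diversity"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- dat[dat$protein == grid$protein[i] & dat$isotype == grid$isotype[i], ]
    x <- d[[grid$measure[i]]][d$group == "allergic"]
    y <- d[[grid$measure[i]]][d$group == "tolerant"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) {
      return(data.frame(visit = visit, isotype = grid$isotype[i],
                        protein = grid$protein[i], measure = grid$measure[i],
                        n_allergic = length(x), n_tolerant = length(y),
                        direction = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- if (stats::var(c(x, y)) == 0) {
      1  # every observation tied across groups: no evidence either way
    } else {
      suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                          exact = FALSE, correct = TRUE))$p.value
    }
    data.frame(visit = visit, isotype = grid$isotype[i],
               protein = grid$protein[i], measure = grid$measure[i],
               n_allergic = length(x), n_tolerant = length(y),
               direction = sign(stats::median(x) - stats::median(y)),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q < alpha
  out[order(match(out$protein, .PROTEIN_ORDER), out$isotype, out$measure), ,
      drop = FALSE]
}
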