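#' Load the bundled mature milk-allergen sequences
#'
#' Reads the FASTA of the five major cow's-milk allergens (mature chains,
#' signal peptides removed): αS1-, αS2-, β- and κ-casein and
#' β-lactoglobulin. The bundled sequences are canonical-sequence
#' reconstructions of the mature chains; the tiling of these chains with
#' a 20-residue window and 3-residue offset yields the array's
#' 61/64/64/51/49 peptides per protein.
#'
#' @param path FASTA file; defaults to the bundled fixture.
#' @return [Biostrings::AAStringSet] named by ASCII allergen label, with
#'   an `iuis` element in `metadata()`.
#' @examples
#' prots <- milkAllergens()
#' lengths(prots)
#' @export
milkAllergens <- function(path = system.file("extdata", "milk_allergens.fasta",
                                             package = "milkEpimap")) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("[[:space:]].*$", "", names(aa))
  iuis <- sub("^.*iuis=([^[:space:]]+).*$", "\\1", names(aa))
  names(aa) <- .normalizeProtein(ids)
  aa <- aa[intersect(.PROTEIN_ORDER, names(aa))]
  S4Vectors::metadata(aa)$iuis <- gsub("_", " ", iuis[match(names(aa), ids)])
  aa
}

#' Tile one protein into overlapping peptides
#'
#' Generates the overlapping-peptide windows for a single protein:
#' windows of `window` residues starting at positions 1, 1+offset,
#' 1+2·offset, ... for as long as they fit, plus — when the last regular
#' window does not end exactly at the C-terminus — one additional
#' peptide covering the final `window` residues, so that the tiling
#' always ends flush with the protein.
#'
#' @param sequence amino-acid string (or length-1 `AAStringSet`/
#'   `AAString`) of the mature chain; standard 20 residues only.
#' @param protein allergen label for the output records.
#' @param window peptide length in residues (default 20).
#' @param offset tiling offset in residues (default 3).
#' @return data.frame with columns `protein`, `index`, `start`, `end`,
#'   `sequence`, `key`; one row per peptide, `index` running 1..N.
#' @examples
#' tileProtein(paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = ""), "b-lac")
#' @export
tileProtein <- function(sequence, protein, window = 20L, offset = 3L) {
  if (methods::is(sequence, "XStringSet")) sequence <- as.character(sequence[[1L]])
  if (methods::is(sequence, "XString")) sequence <- as.character(sequence)
  sequence <- toupper(as.character(sequence))
  window <- as.integer(window); offset <- as.integer(offset)
  stopifnot(window >= 1L, offset >= 1L)
  protein <- .normalizeProtein(protein)

  res <- strsplit(sequence, "")[[1L]]
  bad <- which(!(res %in% .AA_STANDARD))
  if (length(bad)) {
    stop(sprintf("non-standard residue '%s' at position %d of %s",
                 res[bad[1L]], bad[1L], protein))
  }
  L <- length(res)
  if (L < window) {
    stop(sprintf("%s sequence (%d aa) is shorter than the window (%d aa): unusable protein",
                 protein, L, window))
  }

  starts <- seq.int(1L, L - window + 1L, by = offset)
  if (starts[length(starts)] + window - 1L < L) {
    # terminal peptide: last full window, flush with the C-terminus
    starts <- c(starts, L - window + 1L)
  }
  ends <- starts + window - 1L
  data.frame(
    protein = protein,
    index = seq_along(starts),
    start = starts,
    end = ends,
    sequence = substring(sequence, starts, ends),
    key = peptideKey(protein, seq_along(starts)),
    stringsAsFactors = FALSE
  )
}

#' Build the full peptide library across allergens
#'
#' Concatenates per-protein tilings in the fixed display order
#' αs1-cas, αs2-cas, β-cas, κ-cas, β-lac. With the bundled mature
#' chains and the default window/offset this reproduces the printed
#' array content: 61 + 64 + 64 + 51 + 49 = 289 peptides.
#'
#' @param proteins named character vector or `AAStringSet` of mature
#'   sequences; names are allergen labels (defaults to
#'   [milkAllergens()]).
#' @param window,offset tiling parameters passed to [tileProtein()].
#' @return a [PeptideLibrary-class]
#' @examples
#' lib <- buildLibrary()
#' table(peptides(lib)$protein)
#' @export
buildLibrary <- function(proteins = milkAllergens(), window = 20L, offset = 3L) {
  if (methods::is(proteins, "XStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  if (is.null(names(proteins)) || any(names(proteins) == "")) {
    stop("proteins must be named by allergen label")
  }
  labels <- .normalizeProtein(names(proteins))
  if (anyDuplicated(labels)) stop("duplicate protein name(s)")
  ord <- order(match(labels, .PROTEIN_ORDER))
  tiles <- lapply(ord, function(i) {
    tileProtein(proteins[[i]], labels[i], window = window, offset = offset)
  })
  pep <- do.call(rbind, tiles)
  methods::new("PeptideLibrary",
    peptides = S4Vectors::DataFrame(pep),
    window = as.integer(window),
    offset = as.integer(offset)
  )
}

#' @describeIn PeptideLibrary-class peptide table as a data.frame
#' @param object,x a `PeptideLibrary`
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname PeptideLibrary-class
#' @export
setMethod("peptides", "PeptideLibrary", function(x) {
  as.data.frame(x@peptides)
})

#' @describeIn PeptideLibrary-class feature keys in library order
#' @export
setGeneric("peptideKeys", function(x) standardGeneric("peptideKeys"))

#' @rdname PeptideLibrary-class
#' @export
setMethod("peptideKeys", "PeptideLibrary", function(x) as.character(x@peptides$key))

#' @rdname PeptideLibrary-class
#' @export
setMethod("length", "PeptideLibrary", function(x) nrow(x@peptides))

setMethod("show", "PeptideLibrary", function(object) {
  tab <- table(factor(object@peptides$protein, levels = .PROTEIN_ORDER))
  cat(sprintf("PeptideLibrary: %d peptides (window %d aa, offset %d aa)\n",
              nrow(object@peptides), object@window, object@offset))
  for (p in names(tab)) {
    if (tab[[p]] > 0L) {
      cat(sprintf("  %-8s (%s): %d peptides\n",
                  .displayProtein(p), .IUIS_NAMES[[p]], tab[[p]]))
    }
  }
})

#' Name an epitope region by protein and peptide-index range
#'
#' Field convention for naming merged epitope regions, e.g.
#' `"αs1-cas 3"` for a single peptide and `"κ-cas 29–31"` for a run of
#' contiguous peptides (en dash between first and last index).
#'
#' @param protein allergen label.
#' @param first,last 1-based peptide indices, `first <= last`.
#' @param library optional [PeptideLibrary-class]; when supplied, the
#'   indices are checked against the protein's peptide count.
#' @return character region name (Greek display label).
#' @examples
#' regionName("k-cas", 29, 31)
#' @export
regionName <- function(protein, first, last = first, library = NULL) {
  protein <- .normalizeProtein(protein)
  first <- as.integer(first); last <- as.integer(last)
  if (first < 1L || first > last) stop("need 1 <= first <= last")
  if (!is.null(library)) {
    nmax <- sum(peptides(library)$protein == protein)
    if (last > nmax) {
      stop(sprintf("index %d out of range for %s (%d peptides)", last, protein, nmax))
    }
  }
  disp <- .displayProtein(protein)
  if (first == last) sprintf("%s %d", disp, first)
  else sprintf("%s %d–%d", disp, first, last)
}

#' Write a peptide library as TSV
#'
#' @param library a [PeptideLibrary-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeLibraryTSV <- function(library, path) {
  utils::write.table(peptides(library), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
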