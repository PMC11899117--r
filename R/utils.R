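# Internal label handling shared across modules.

# Fixed display order of the five allergens on the array.
.PROTEIN_ORDER <- c("as1-cas", "as2-cas", "b-cas", "k-cas", "b-lac")

.PROTEIN_DISPLAY <- c(
  "as1-cas" = "αs1-cas",
  "as2-cas" = "αs2-cas",
  "b-cas"   = "β-cas",
  "k-cas"   = "κ-cas",
  "b-lac"   = "β-lac"
)

.IUIS_NAMES <- c(
  "as1-cas" = "Bos d 9",
  "as2-cas" = "Bos d 10",
  "b-cas"   = "Bos d 11",
  "k-cas"   = "Bos d 12",
  "b-lac"   = "Bos d 5"
)

# Accepts either the ASCII label used in files ("as1-cas") or the Greek
# display label ("αs1-cas"); returns the ASCII form.
.normalizeProtein <- function(x) {
  x <- as.character(x)
  rev_map <- stats::setNames(names(.PROTEIN_DISPLAY), .PROTEIN_DISPLAY)
  hit <- !is.na(rev_map[x])
  x[hit] <- rev_map[x[hit]]
  bad <- !(x %in% .PROTEIN_ORDER)
  if (any(bad)) {
    stop("unknown allergen label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

.displayProtein <- function(x) {
  unname(.PROTEIN_DISPLAY[.normalizeProtein(x)])
}

#' Peptide feature key
#'
#' Builds the ASCII feature identifier used in spot tables and matrix
#' dimnames, e.g. `"as1-cas_p3"`. The inverse mapping is performed by the
#' readers, which split on the final `"_p"`.
#'
#' @param protein allergen label (ASCII or Greek display form)
#' @param index 1-based peptide ordinal within the protein
#' @return character vector of keys
#' @export
peptideKey <- function(protein, index) {
  paste0(.normalizeProtein(protein), "_p", as.integer(index))
}

.splitKey <- function(key) {
  m <- regmatches(key, regexec("^(.*)_p([0-9]+)$", key))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed peptide key(s): ", paste(key[bad], collapse = ", "))
  data.frame(
    protein = vapply(m, `[`, "", 2L),
    index = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

.AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
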