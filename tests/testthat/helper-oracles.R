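# Brute-force oracles, written independently of the package's
# implementation paths, plus small fixture generators.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# all tiling windows by direct enumeration: regular offsets, then the
# flush C-terminal window if the last regular one falls short
oracle_tile_starts <- function(L, window, offset) {
  starts <- integer(0)
  s <- 1L
  while (s + window - 1L <= L) {
    starts <- c(starts, s)
    s <- s + offset
  }
  if (starts[length(starts)] + window - 1L < L) starts <- c(starts, L - window + 1L)
  starts
}

# spot-by-spot standardization and plain mean over usable replicates
oracle_zscores <- function(spots, location, scale, keys) {
  vapply(keys, function(k) {
    rows <- spots[spots$feature_id == k & spots$flag == "ok", , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_real_)
    mean((rows$intensity - location) / scale)
  }, numeric(1))
}

oracle_controls <- function(pbs) {
  m <- sum(pbs) / length(pbs)
  list(location = m, scale = sqrt(sum((pbs - m)^2) / length(pbs)))
}

# cell-by-cell protein summaries from a z matrix (peptides x patients)
oracle_summary <- function(z, protein_of) {
  out <- list()
  for (p in unique(protein_of)) {
    for (j in seq_len(ncol(z))) {
      cells <- z[protein_of == p, j]
      cells <- cells[!is.na(cells)]
      out[[length(out) + 1L]] <- data.frame(
        patient = colnames(z)[j], protein = p,
        intensity = if (length(cells)) mean(cells) else NA_real_,
        diversity = if (length(cells)) sum(cells > 3) else NA_integer_
      )
    }
  }
  do.call(rbind, out)
}

# threshold scan: fraction of allergic patients with a positive call
oracle_informative <- function(z, allergic, threshold = 0.75) {
  hits <- character(0)
  for (i in seq_len(nrow(z))) {
    calls <- z[i, allergic]
    calls <- calls[!is.na(calls)]
    if (length(calls) && sum(calls > 3) / length(calls) > threshold) {
      hits <- c(hits, rownames(z)[i])
    }
  }
  hits
}

# naive O(n^3) UPGMA on a distance matrix; returns merge heights
oracle_upgma_heights <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(members) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (a >= b) next
        d <- mean(D[members[[a]], members[[b]]])
        if (d < bestd - 1e-12) { bestd <- d; best <- c(a, b) }
      }
    }
    heights <- c(heights, bestd)
    members[[best[1L]]] <- c(members[[best[1L]]], members[[best[2L]]])
    members[[best[2L]]] <- NULL
  }
  heights
}

# a toy two-protein library (labels reused from the real panel; the
# sequences are random) for matrix-level fixtures
toy_library <- function(len1 = 26L, len2 = 29L) {
  buildLibrary(c("as1-cas" = random_aa(len1), "b-lac" = random_aa(len2)))
}

# random one-array spot table over the given keys: duplicate peptide
# spots, 4 PBS spots, occasional bad flags
random_array <- function(keys, pid = "P1", visit = 1L, isotype = "IgE",
                         p_bad = 0) {
  n <- length(keys)
  pep <- data.frame(
    patient_id = pid, visit = visit, isotype = isotype,
    feature_id = rep(keys, each = 2L), replicate = rep(1:2, n),
    intensity = stats::runif(2L * n, 50, 400),
    flag = ifelse(stats::runif(2L * n) < p_bad, "bad", "ok"),
    stringsAsFactors = FALSE
  )
  pbs <- data.frame(
    patient_id = pid, visit = visit, isotype = isotype,
    feature_id = "PBS", replicate = 1:4,
    intensity = stats::rnorm(4L, 200, 30), flag = "ok",
    stringsAsFactors = FALSE
  )
  rbind(pep, pbs)
}
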