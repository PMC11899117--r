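make_bm <- function(z, lib, isotype = "IgE", visit = 1L) {
  colnames(z) <- sprintf("P%02d", seq_len(ncol(z)))
  BindingMatrix(z, lib, isotype, visit)
}

test_that("protein summaries match hand arithmetic", {
  lib <- toy_library()  # 3 + 4 peptides
  n1 <- sum(peptides(lib)$protein == "as1-cas")
  z <- matrix(0, length(lib), 4)
  bm <- make_bm(z, lib)
  s <- summarizeProtein(bm)
  expect_true(all(s$intensity == 0) && all(s$diversity == 0))

  # one protein with cells {4, 4, 2}: intensity 10/3, diversity 2
  expect_equal(n1, 3L)
  z2 <- z
  z2[1:3, 1] <- c(4, 4, 2)
  s2 <- summarizeProtein(make_bm(z2, lib))
  r <- s2[s2$patient_id == "P01" & s2$protein == "as1-cas", ]
  expect_equal(r$intensity, 10 / 3)
  expect_equal(r$diversity, 2)

  # all-missing protein: both measures missing
  z3 <- z
  z3[1:3, 2] <- NA
  s3 <- summarizeProtein(make_bm(z3, lib))
  r3 <- s3[s3$patient_id == "P02" & s3$protein == "as1-cas", ]
  expect_true(is.na(r3$intensity) && is.na(r3$diversity))
})

test_that("protein summaries agree with the brute-force oracle", {
  set.seed(14)
  lib <- toy_library(32, 41)
  prot <- peptides(lib)$protein
  for (r in 1:25) {
    z <- matrix(rnorm(length(lib) * 6, 0, 2), length(lib))
    z[sample(length(z), 8)] <- NA
    bm <- make_bm(z, lib)
    s <- summarizeProtein(bm)
    o <- oracle_summary(zscores(bm), prot)
    m <- merge(s, o, by.x = c("patient_id", "protein"),
               by.y = c("patient", "protein"))
    expect_equal(m$intensity.x, m$intensity.y, tolerance = 1e-9)
    expect_equal(m$diversity.x, as.numeric(m$diversity.y))
  }
})

test_that("informativeness requires strictly more than 75% of allergic patients", {
  lib <- toy_library()
  z <- matrix(0, length(lib), 5)
  z[1, 1:3] <- 5            # 3 of 4 allergic positive -> exactly 0.75
  z[2, 1:4] <- 5            # 4 of 4 allergic positive
  bm <- make_bm(z, lib)
  labels <- data.frame(patient_id = sprintf("P%02d", 1:5), visit = 1,
                       status = c(rep("allergic", 4), "tolerant"))
  inf <- informativePeptides(bm, labels, 1)
  expect_false(peptideKeys(lib)[1] %in% inf$key)
  expect_true(peptideKeys(lib)[2] %in% inf$key)
  expect_equal(inf$fraction[inf$key == peptideKeys(lib)[2]], 1.0)
  # no allergic patients -> no reference group
  expect_error(
    informativePeptides(bm, data.frame(patient_id = "P01", visit = 1,
                                       status = "tolerant"), 1),
    "no reference group")
})

test_that("informativeness matches a brute-force threshold scan and is monotone", {
  set.seed(8)
  lib <- toy_library(35, 38)
  labels <- data.frame(patient_id = sprintf("P%02d", 1:20), visit = 2,
                       status = sample(c("allergic", "tolerant"), 20, TRUE))
  for (r in 1:25) {
    z <- matrix(rnorm(length(lib) * 20, 2, 2), length(lib))
    z[sample(length(z), 15)] <- NA
    bm <- make_bm(z, lib, visit = 2L)
    inf <- informativePeptides(bm, labels, 2)
    allergic <- labels$patient_id[labels$status == "allergic"]
    expect_identical(inf$key, oracle_informative(zscores(bm), allergic))

    # adding a positive call for an allergic patient never removes a peptide
    z2 <- z
    i <- sample(length(lib), 1)
    j <- match(sample(allergic, 1), colnames(zscores(bm)))
    z2[i, j] <- 10
    inf2 <- informativePeptides(make_bm(z2, lib, visit = 2L), labels, 2)
    expect_true(all(inf$key %in% inf2$key))
  }
})

test_that("contiguous informative peptides merge into named regions", {
  lib <- buildLibrary()
  inf <- data.frame(visit = 3, isotype = "IgE",
                    key = peptideKey("as1-cas", c(3, 16, 17, 18)),
                    protein = "as1-cas", index = c(3L, 16:18),
                    fraction = c(0.8, 0.9, 0.85, 0.95), n_allergic = 20)
  reg <- mergeContiguous(inf, lib)
  expect_equal(reg$region, c("αs1-cas 3", "αs1-cas 16–18"))
  expect_equal(reg$n_peptides, c(1L, 3L))
  expect_equal(reg$min_fraction, c(0.8, 0.85))
  # partition-preserving: every peptide in exactly one region
  expect_equal(sum(reg$n_peptides), nrow(inf))
  # empty in, empty out
  expect_equal(nrow(mergeContiguous(inf[0, ], lib)), 0L)
})

test_that("persistent epitopes are those informative at every visit", {
  lib <- buildLibrary()
  mk <- function(idx, visit) data.frame(
    visit = visit, isotype = "IgE", key = peptideKey("k-cas", idx),
    protein = "k-cas", index = as.integer(idx),
    fraction = 0.9, n_allergic = 30)
  pv <- list(mk(c(29, 30, 31, 40), 1), mk(c(29, 30, 31), 2), mk(c(29, 30, 31, 7), 3))
  per <- persistentEpitopes(pv, lib)
  expect_equal(per$region, "κ-cas 29–31")  # 40 missing at visit 2 -> excluded
  expect_true(all(is.na(per$visit)))
  expect_error(persistentEpitopes(pv[1], lib))
})

test_that("group comparisons behave at the null and under strict separation", {
  lib <- toy_library()
  labels <- data.frame(patient_id = sprintf("P%02d", 1:20), visit = 2,
                       status = rep(c("allergic", "tolerant"), each = 10))
  # identical group distributions -> no significant comparison
  z <- matrix(rep(rnorm(length(lib) * 10), 2), length(lib))
  s <- summarizeProtein(make_bm(z, lib, visit = 2L))
  cmp <- compareGroups(s, labels, 2)
  expect_true(all(cmp$q > 0.9))
  expect_false(any(cmp$significant))

  # complete separation, n = 10 vs 10, no ties -> p < 0.001, direction +1
  z2 <- cbind(matrix(rnorm(length(lib) * 10, 20, 1), length(lib)),
              matrix(rnorm(length(lib) * 10, 0, 1), length(lib)))
  s2 <- summarizeProtein(make_bm(z2, lib, visit = 2L))
  cmp2 <- compareGroups(s2, labels, 2)
  intens <- cmp2[cmp2$measure == "intensity", ]
  expect_true(all(intens$p < 0.001))
  expect_true(all(intens$direction == 1))

  # a group empty at the visit -> not evaluable
  lab1 <- labels; lab1$status <- "allergic"
  cmp3 <- compareGroups(s2, lab1, 2)
  expect_true(all(is.na(cmp3$p)))

  # baseline grouping uses the 6-month outcome
  zb <- z2
  sb <- summarizeProtein(make_bm(zb, lib, visit = 1L))
  labs <- rbind(labels, data.frame(patient_id = sprintf("P%02d", 1:20),
                                   visit = 1, status = "allergic"))
  cmpb <- compareGroups(sb, labs, 1)
  expect_true(all(cmpb$p[cmpb$measure == "intensity"] < 0.001))
})
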