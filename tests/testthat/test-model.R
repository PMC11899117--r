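toy_cohort <- function() {
  data.frame(
    patient_id = c("A", "B", "C", "D"),
    milk_sige = c(1, 2, 3, 4), alac_sige = 1, blg_sige = 1, casein_sige = 1,
    total_ige = 10, casein_sigg4 = 0.1, blg_sigg4 = 0.1, alac_sigg4 = 0.1,
    # A tolerant at 2; B lost after visit 2 while allergic;
    # C allergic throughout; D tolerant at 4
    first_tolerant_visit = c(2L, NA, NA, 4L),
    last_visit = c(2L, 2L, 6L, 4L),
    stringsAsFactors = FALSE
  )
}

test_that("accumulative tolerance labels behave across target visits", {
  ch <- toy_cohort()
  o2 <- assignOutcome(ch, 2)
  o3 <- assignOutcome(ch, 3)
  o4 <- assignOutcome(ch, 4)
  expect_equal(as.character(o2[["A"]]), "tolerant")
  expect_equal(as.character(o3[["A"]]), "tolerant")  # tolerant at or before
  expect_equal(as.character(o4[["A"]]), "tolerant")
  expect_equal(as.character(o2[["B"]]), "allergic")
  expect_true(is.na(o3[["B"]]) && is.na(o4[["B"]]))  # lost while allergic
  expect_equal(unname(as.character(o4[c("C", "D")])), c("allergic", "tolerant"))
  expect_error(assignOutcome(ch, 7), "unknown visit")
  expect_error(assignOutcome(ch, 5), "refused")
  expect_s3_class(assignOutcome(ch, 5, allowLate = TRUE), "factor")
})

test_that("visit labels satisfy the accumulative-tolerance invariants", {
  lab <- visitLabels(toy_cohort())
  expect_true(all(lab$status[lab$visit == 1] == "allergic"))
  # once tolerant, tolerant at all later visits
  for (p in unique(lab$patient_id)) {
    st <- lab$status[lab$patient_id == p][order(lab$visit[lab$patient_id == p])]
    tol <- which(st == "tolerant")
    if (length(tol)) expect_true(all(st[seq(min(tol), length(st))] == "tolerant"))
  }
  # lost patients have no status after withdrawal
  expect_false(any(lab$patient_id == "B" & lab$visit > 2))
})

test_that("confusion metrics match hand arithmetic", {
  m <- confusionMetrics(8, 2, 2, 18)
  expect_equal(unname(m["precision"]), 0.8)
  expect_equal(unname(m["recall"]), 0.8)
  expect_equal(unname(m["f1"]), 0.8)
  expect_equal(unname(m["accuracy"]), 26 / 30)
  expect_equal(unname(confusionMetrics(0, 0, 3, 7)[c("precision", "f1")]), c(0, 0))
})

test_that("feature tables use baseline data only", {
  lib <- toy_library()
  set.seed(2)
  ids <- sprintf("P%03d", 1:12)
  ch <- data.frame(patient_id = ids, milk_sige = runif(12), alac_sige = runif(12),
                   blg_sige = runif(12), casein_sige = runif(12),
                   total_ige = runif(12, 5, 30), casein_sigg4 = runif(12),
                   blg_sigg4 = runif(12), alac_sigg4 = runif(12),
                   first_tolerant_visit = rep(c(2L, 3L, NA), 4),
                   last_visit = rep(c(2L, 3L, 6L), 4))
  z <- matrix(rnorm(length(lib) * 12), length(lib),
              dimnames = list(NULL, ids))
  bms <- list(IgE = BindingMatrix(z, lib, "IgE", 1),
              IgG4 = BindingMatrix(z + 1, lib, "IgG4", 1))
  ft <- buildFeatureTable(ch, bms, 3)
  expect_true(all(grepl("^(IgE|IgG4)_", setdiff(colnames(ft),
                                                c("outcome", "milk_sige", "alac_sige",
                                                  "blg_sige", "casein_sige", "total_ige",
                                                  "casein_sigg4", "blg_sigg4", "alac_sigg4")))))
  # shuffling post-baseline outcomes changes labels, never feature values
  ch2 <- ch
  ch2$first_tolerant_visit <- rep(c(3L, 2L, NA), 4)
  ft2 <- buildFeatureTable(ch2, bms, 3)
  shared <- intersect(rownames(ft), rownames(ft2))
  expect_equal(ft[shared, setdiff(colnames(ft), "outcome")],
               ft2[shared, setdiff(colnames(ft2), "outcome")])
  # a visit-2 matrix is rejected as a leakage hazard
  expect_error(buildFeatureTable(ch, list(IgE = BindingMatrix(z, lib, "IgE", 2)), 3))
})

test_that("the trainer is seed-reproducible and rejects degenerate outcomes", {
  grid <- data.frame(max_depth = 2L, eta = 0.3, min_child_weight = 1,
                     nrounds = 40L)
  ft <- plantedFeatureTable(nPatients = 60, nFeatures = 30, nInformative = 5,
                            effectSize = 1.5, seed = 10)
  r1 <- trainEvaluate(ft, 2, seed = 5, grid = grid, nfold = 5)
  r2 <- trainEvaluate(ft, 2, seed = 5, grid = grid, nfold = 5)
  expect_identical(modelMetrics(r1), modelMetrics(r2))
  expect_identical(r1@importance, r2@importance)
  expect_true(all(modelMetrics(r1)[c("f1", "precision", "recall", "accuracy")] >= 0))

  bad <- ft
  bad$outcome <- factor("allergic", levels = c("allergic", "tolerant"))
  expect_error(trainEvaluate(bad, 2, seed = 1, grid = grid), "degenerate outcome")
})

test_that("a strong planted signal is learned and its features ranked on top", {
  grid <- data.frame(max_depth = 3L, eta = 0.1, min_child_weight = 1,
                     nrounds = 100L)
  ft <- plantedFeatureTable(seed = 77)  # 10 informative of 586, d = 2
  rep <- trainEvaluate(ft, 2, seed = 77, grid = grid)
  expect_gte(unname(modelMetrics(rep)["test_auc"]), 0.9)
  top <- importanceReport(rep, 10)
  expect_equal(nrow(top), 10L)
  expect_gte(sum(top$feature %in% paste0("f", 1:10)), 8L)
  expect_equal(sum(top$share_of_reported), 1)

  # a single informative feature takes essentially all the gain
  ft1 <- plantedFeatureTable(nPatients = 80, nFeatures = 12, nInformative = 1,
                             effectSize = 3, seed = 3)
  rep1 <- trainEvaluate(ft1, 2, seed = 3, grid = grid)
  expect_equal(importanceReport(rep1, 1)$feature, "f1")
  expect_gt(importanceReport(rep1, 1)$gain, 0.5)
  # topK above the variable count returns all variables
  expect_equal(nrow(importanceReport(rep1, 50)), 12L)
})
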