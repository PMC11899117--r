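test_that("the CSV dialect reads a full array as 582 records", {
  lib <- buildLibrary()
  set.seed(3)
  arr <- random_array(peptideKeys(lib))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpotCSV(arr[setdiff(names(arr), "replicate")], f)
  spots <- readSpotTable(f, "csv")
  expect_equal(nrow(spots), 2L * 289L + 4L)  # duplicates of 289 peptides + 4 PBS
  expect_equal(sum(spots$feature_id == "PBS"), 4L)
  # replicate numbers re-assigned in file order
  expect_equal(as.vector(table(spots$replicate[spots$feature_id != "PBS"])),
               c(289L, 289L))
})

test_that("reader errors and QC findings are reported", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,visit,isotype,feature_id,intensity", f)
  expect_error(readSpotTable(f, "csv"), "no records")
  writeLines(c("patient_id,visit,feature_id,intensity", "P1,1,x,2"), f)
  expect_error(readSpotTable(f, "csv"), "isotype")
  expect_error(readSpotTable(file.path(tempdir(), "absent.csv"), "csv"), "not found")

  # one flagged replicate: record kept with flag bad, QC warning recorded
  lib <- toy_library()
  set.seed(9)
  arr <- random_array(peptideKeys(lib))
  arr$flag[1L] <- "bad"
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeSpotCSV(arr, f2)
  spots <- readSpotTable(f2, "csv", library = lib)
  expect_equal(spots$flag[1L], "bad")
  expect_match(qcReport(spots), "flagged bad", all = FALSE)
  expect_match(qcReport(spots), "without exactly 2", all = FALSE)
})

test_that("the GPR dialect parses the ATF header block and flag mapping", {
  gpr <- c(
    "ATF\t1.0", "4\t5",
    "\"Type=GenePix Results 3\"", "\"DateTime=2010/06/01\"",
    "\"Wavelengths=532\"", "\"PMTGain=600\"",
    paste("Block", "ID", "Name", "F532 Median - B532", "Flags", sep = "\t"),
    paste(1, "as1-cas_p1", "peptide", 150, 0, sep = "\t"),
    paste(1, "as1-cas_p1", "peptide", 160, 0, sep = "\t"),
    paste(1, "PBS", "control", 95, 0, sep = "\t"),
    paste(1, "PBS", "control", 105, -50, sep = "\t")
  )
  f <- withr::local_tempfile(fileext = ".gpr")
  writeLines(gpr, f)
  expect_error(readSpotTable(f, "gpr"), "patient_id")
  spots <- readSpotTable(f, "gpr", patient_id = "P9", visit = 2, isotype = "IgG4")
  expect_equal(nrow(spots), 4L)
  expect_equal(spots$intensity, c(150, 160, 95, 105))
  expect_equal(spots$flag, c("ok", "ok", "ok", "bad"))
  expect_equal(unique(spots$patient_id), "P9")
  expect_error(readSpotTable(f, "gpr", patient_id = "P9", visit = 2,
                             isotype = "IgG4", intensityColumn = "F635 Median"),
               "missing required")
})

test_that("control fitting uses the population formula and rejects degenerate arrays", {
  expect_error(fitControls(c(100, 100, 100, 100)), "degenerate controls")
  expect_error(fitControls(c(100)), "insufficient controls")
  ctl <- fitControls(c(90, 110))
  expect_equal(ctl$location, 100)
  expect_equal(ctl$scale, 10)  # population SD, not sample SD
  # Monte-Carlo recovery within 5%
  set.seed(11)
  big <- rnorm(1000, 250, 40)
  ctl2 <- fitControls(big)
  expect_lt(abs(ctl2$location - 250) / 250, 0.05)
  expect_lt(abs(ctl2$scale - 40) / 40, 0.05)
  # robust variant
  ctl3 <- fitControls(c(90, 100, 110, 1e6), robust = TRUE)
  expect_equal(ctl3$location, 105)
})

test_that("weighted average Z-scores match hand arithmetic and flag weighting", {
  ctl <- structure(list(location = 100, scale = 10, n = 4),
                   class = "ControlDistribution")
  spots <- data.frame(patient_id = "P1", visit = 1, isotype = "IgE",
                      feature_id = rep(c("a_p1", "a_p2", "a_p3"), each = 2),
                      replicate = rep(1:2, 3),
                      intensity = c(130, 130, 120, 900, 105, 111),
                      flag = c("ok", "ok", "ok", "bad", "bad", "bad"))
  z <- computeZscores(spots, ctl, keys = c("a_p1", "a_p2", "a_p3"))
  expect_equal(unname(z["a_p1"]), 3.0)
  expect_equal(unname(z["a_p2"]), 2.0)   # bad replicate carries weight 0
  expect_true(is.na(z["a_p3"]))          # zero total weight -> missing cell
})

test_that("Z-score computation agrees with the brute-force oracle on random arrays", {
  set.seed(21)
  keys <- paste0("as1-cas_p", 1:12)
  for (r in 1:40) {
    arr <- random_array(keys, p_bad = 0.15)
    ctl <- fitControls(arr)
    ctl_o <- oracle_controls(arr$intensity[arr$feature_id == "PBS"])
    expect_equal(ctl$location, ctl_o$location, tolerance = 1e-12)
    expect_equal(ctl$scale, ctl_o$scale, tolerance = 1e-12)
    z <- computeZscores(arr, ctl, keys = keys)
    expect_equal(z, oracle_zscores(arr, ctl$location, ctl$scale, keys),
                 tolerance = 1e-9)
  }
})

test_that("standardization is location-scale equivariant", {
  set.seed(5)
  keys <- paste0("b-lac_p", 1:10)
  arr <- random_array(keys, p_bad = 0.1)
  z1 <- computeZscores(arr, fitControls(arr), keys = keys)
  arr2 <- arr
  arr2$intensity <- 7.5 + 3.2 * arr$intensity
  z2 <- computeZscores(arr2, fitControls(arr2), keys = keys)
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("an array at the control location is all zero with zero diversity", {
  lib <- toy_library()
  keys <- peptideKeys(lib)
  arr <- random_array(keys)
  arr$intensity <- 200
  arr$intensity[arr$feature_id == "PBS"] <- c(190, 210, 195, 205)
  bm <- buildBindingMatrix(arr, lib, "IgE", 1)
  expect_true(all(zscores(bm) == 0))
  expect_true(all(summarizeProtein(bm)$diversity == 0))
})

test_that("positivity is a strict exceedance of three", {
  expect_false(callPositive(3.0))
  expect_true(callPositive(3.000001))
  expect_false(callPositive(-1))
  expect_true(is.na(callPositive(NA)))
})

test_that("binding matrices follow library order and round-trip through TSV", {
  lib <- toy_library()
  set.seed(33)
  arr <- rbind(random_array(peptideKeys(lib), pid = "P1"),
               random_array(peptideKeys(lib), pid = "P2"))
  bm <- buildBindingMatrix(arr, lib, "IgE", 1)
  expect_identical(rownames(zscores(bm)), peptideKeys(lib))
  expect_equal(arrayIsotype(bm), "IgE")
  expect_equal(arrayVisit(bm), 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeBindingTSV(bm, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(as.matrix(back[-1]), t(zscores(bm)), tolerance = 1e-9,
               ignore_attr = TRUE)
})
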