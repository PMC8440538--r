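bupLibrary <- function() {
  data.frame(
    precursor = "bupropion",
    metabolite_name = c("bupropion", "hydroxybupropion"),
    formula = c("C13H18ClNO", "C13H18ClNO2"),
    adduct = "[M+H]+",
    theoretical_mz = c(240.1150, 256.1099),
    method = "HILIC+", rt = c(80, 85),
    ms2_id = NA_character_, evidence = NA_character_, msi_level = 3L,
    stringsAsFactors = FALSE)
}

test_that("library matching enforces both ppm and RT windows", {
  lib <- bupLibrary()
  tab <- makeTable(
    mz = c(256.1095, 256.1099, 256.1110),
    rt = c(84, 95, 85),
    intensities = matrix(1e5, 3, 1, dimnames = list(NULL, "s1")),
    sampleData = data.frame(sample_id = "s1"),
    ids = c("inWindow", "rtOut", "ppmOut"))
  m <- matchLibrary(tab, lib)
  expect_identical(m$feature_id, "inWindow")
  expect_equal(m$ppm_error, ppmError(256.1095, 256.1099))
  expect_equal(m$delta_rt, -1)
  # widening tolerances never removes matches
  wide <- matchLibrary(tab, lib, ppmTol = 10, rtTol = 20)
  expect_true(all(paste(m$feature_id, m$metabolite_name) %in%
                  paste(wide$feature_id, wide$metabolite_name)))
  expect_true(all(c("rtOut", "ppmOut") %in% wide$feature_id))
})

test_that("method mismatch excludes entries from matching", {
  lib <- bupLibrary()
  lib$method <- "C18-"
  tab <- makeTable(mz = 256.1099, rt = 85,
                   intensities = matrix(1e5, 1, 1,
                                        dimnames = list(NULL, "s1")),
                   sampleData = data.frame(sample_id = "s1"), ids = "f")
  expect_identical(nrow(matchLibrary(tab, lib)), 0L)
})

test_that("presence matrix min-max scales within rows and groups precursors", {
  lib <- bupLibrary()
  m <- matrix(c(10, 100, 40, NA, 0, 50), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  tab <- makeTable(mz = c(240.1150, 256.1099), rt = c(80, 85),
                   intensities = m,
                   sampleData = data.frame(sample_id = c("a", "b", "c")),
                   ids = c("f1", "f2"))
  pres <- presenceMatrix(matchLibrary(tab, lib), tab)
  expect_identical(dim(pres$detected), c(2L, 3L))
  bup <- pres$relative["bupropion: bupropion", ]
  expect_equal(unname(bup), c(0, 1, (40 - 10) / 90))
  # zero intensity is not detected; its relative value is NA
  expect_false(pres$detected["bupropion: hydroxybupropion", "b"])
  expect_true(is.na(pres$relative["bupropion: hydroxybupropion", "b"]))
  expect_identical(pres$precursor, c("bupropion", "bupropion"))

  # degenerate 1x1 case: constant row scales to 1
  one <- presenceMatrix(matchLibrary(tab, lib)[1, , drop = FALSE][
    , , drop = FALSE], tab)
  expect_true(all(one$relative[!is.na(one$relative)] >= 0))

  # empty matches give an empty matrix
  none <- presenceMatrix(matchLibrary(tab, lib[0, ]), tab)
  expect_identical(nrow(none$detected), 0L)
})

test_that("a single detected metabolite in one sample scales to 1", {
  lib <- bupLibrary()[2, ]
  tab <- makeTable(mz = 256.1099, rt = 85,
                   intensities = matrix(5e4, 1, 1,
                                        dimnames = list(NULL, "s1")),
                   sampleData = data.frame(sample_id = "s1"), ids = "f")
  pres <- presenceMatrix(matchLibrary(tab, lib), tab)
  expect_identical(dim(pres$relative), c(1L, 1L))
  expect_equal(pres$relative[1, 1], 1)
})

test_that("confidence levels follow the orthogonal-criteria count", {
  expect_identical(confidenceLevel(c(0L, 1L, 2L, 3L, 4L, 5L)),
                   c(NA_integer_, 3L, 2L, 1L, 1L, 1L))
})

test_that("criteria flags drive levels: co-occurrence lifts to level 1", {
  lib <- bupLibrary()
  # sample a: both related metabolites detected; sample b: only one
  m <- matrix(c(10, 20, 30, NA), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  tab <- makeTable(mz = c(240.1150, 256.1099), rt = c(80, 85),
                   intensities = m,
                   sampleData = data.frame(sample_id = c("a", "b")),
                   ids = c("f1", "f2"))
  matches <- matchLibrary(tab, lib)
  pres <- presenceMatrix(matches, tab)
  res <- assignConfidence(matches, pres)
  a <- res[res$sample_id == "a", ]
  expect_true(all(a$co_occurrence))
  expect_true(all(a$confidence_level == 1L))   # mass + RT + co-occurrence
  b <- res[res$sample_id == "b", ]
  expect_false(any(b$co_occurrence))
  expect_true(all(b$confidence_level == 2L))   # mass + RT only
})

test_that("unassessed criteria are excluded from the count", {
  lib <- bupLibrary()[2, ]
  tab <- makeTable(mz = 256.1099, rt = 85,
                   intensities = matrix(1e5, 1, 2,
                                        dimnames = list(NULL, c("a", "b"))),
                   sampleData = data.frame(sample_id = c("a", "b")),
                   ids = "f")
  matches <- matchLibrary(tab, lib)
  pres <- presenceMatrix(matches, tab)
  # no exposure records, no MS2: only mass + RT assessable
  res <- assignConfidence(matches, pres)
  expect_true(all(is.na(res$exposure_specific)))
  expect_true(all(res$n_criteria == 2L))
  expect_true(all(res$confidence_level == 2L))

  # exposure records present but the metabolite leaks into an unexposed
  # sample: the exposure criterion fails everywhere
  exposures <- data.frame(sample_id = "a", precursor = "bupropion")
  res2 <- assignConfidence(matches, pres, exposures = exposures)
  expect_false(any(res2$exposure_specific))
  # restricted to exposed samples only, the criterion holds
  tab2 <- makeTable(mz = 256.1099, rt = 85,
                    intensities = matrix(c(1e5, NA), 1, 2,
                                         dimnames = list(NULL, c("a", "b"))),
                    sampleData = data.frame(sample_id = c("a", "b")),
                    ids = "f")
  matches2 <- matchLibrary(tab2, lib)
  pres2 <- presenceMatrix(matches2, tab2)
  res3 <- assignConfidence(matches2, pres2, exposures = exposures)
  expect_true(all(res3$exposure_specific))
  expect_true(all(res3$confidence_level == 1L))
})

test_that("MS2 cosine similarity scores greedy fragment matches", {
  sp <- data.frame(mz = c(77.04, 131.05, 184.05),
                   intensity = c(10, 55, 100))
  self <- ms2Match(sp, sp)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_true(self$match)

  disjoint <- ms2Match(sp, data.frame(mz = c(50.1, 60.2),
                                      intensity = c(5, 10)))
  expect_equal(disjoint$score, 0)
  expect_false(disjoint$match)

  # one extra peak at 5% of base: closed-form cosine 1/sqrt(1 + 0.05^2)
  ref <- rbind(sp, data.frame(mz = 210.1, intensity = 5))
  sp2 <- sp; sp2$intensity <- sp$intensity / max(sp$intensity)
  ref2 <- ref; ref2$intensity <- ref$intensity / max(ref$intensity)
  extra <- ms2Match(sp2, ref2)
  expect_gt(extra$score, 0.99)
  expect_equal(extra$score, 1 / sqrt(1 + 0.05^2 / sum(sp2$intensity^2)),
               tolerance = 1e-9)
  expect_error(ms2Match(sp[0, ], sp), "non-empty")
})

test_that("cross-biofluid concordance counts shared positives", {
  mkPres <- function(detRows) {
    det <- do.call(rbind, detRows)
    colnames(det) <- sprintf("S%03d", 1:10)
    list(detected = det, relative = det * 1,
         precursor = sub("\\..*", "", rownames(det)))
  }
  shared <- c(rep(TRUE, 7), rep(FALSE, 3))
  plasma <- mkPres(list(nicotine.parent = shared, nicotine.cotinine = shared,
                        naphthalene.sulfate = c(TRUE, TRUE, rep(FALSE, 8)),
                        naphthalene.glucuronide = c(TRUE, TRUE,
                                                    rep(FALSE, 8))))
  urine <- mkPres(list(nicotine.parent = shared, nicotine.cotinine = shared,
                       naphthalene.sulfate = c(TRUE, TRUE, TRUE, TRUE,
                                               rep(FALSE, 6)),
                       naphthalene.glucuronide = c(TRUE, TRUE, TRUE, TRUE,
                                                   rep(FALSE, 6))))
  conc <- crossBiofluidConcordance(plasma, urine)
  nic <- conc[conc$precursor == "nicotine", ]
  expect_identical(nic$both, 7L)
  expect_identical(nic$neither, 3L)
  nap <- conc[conc$precursor == "naphthalene", ]
  expect_identical(nap$both, 2L)   # 4 urine positives, 2 also in plasma
  expect_identical(nap$only_b, 2L)

  # disjoint positives
  empty <- mkPres(list(nicotine.parent = rep(FALSE, 10),
                       nicotine.cotinine = rep(FALSE, 10)))
  conc2 <- crossBiofluidConcordance(plasma, empty)
  expect_identical(conc2$both[conc2$precursor == "nicotine"], 0L)
})
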