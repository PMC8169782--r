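test_that("exact-mass annotation finds the planted species", {
  db <- buildLipidDatabase("PC", polarity = "positive")
  sp <- Spectrum(760.585, 1e5)
  ann <- annotatePeaks(sp, db)
  expect_true("PC 34:1" %in% ann$name)
  top <- ann[ann$name == "PC 34:1", ]
  expect_identical(top$adduct[1], "[M+H]+")
  expect_lt(abs(top$ppm[1]), 10)
})

test_that("annotation handles empty input and polarity mismatch", {
  db <- buildLipidDatabase("PC", polarity = "positive")
  expect_identical(nrow(annotatePeaks(Spectrum(), db)), 0L)
  neg <- Spectrum(760.585, 1, polarity = "negative")
  expect_error(annotatePeaks(neg, db), "polarity mismatch")
  ms2 <- Spectrum(184.07, 1, msLevel = 2L, precursorMz = 760.58)
  expect_error(annotatePeaks(ms2, db), "MS1")
})

test_that("no annotation ever exceeds the ppm tolerance", {
  db <- buildLipidDatabase(c("PC", "SM", "TG"), polarity = "positive")
  set.seed(7)
  mzs <- runif(200, 400, 1000)
  ann <- annotatePeaks(Spectrum(mzs, rep(1, 200)), db, tolPpm = 10)
  if (nrow(ann)) expect_true(all(abs(ann$ppm) <= 10))
  ann5 <- annotatePeaks(Spectrum(mzs, rep(1, 200)), db, tolPpm = 5)
  if (nrow(ann5)) expect_true(all(abs(ann5$ppm) <= 5))
})

test_that("noise-free simulated spectra are fully annotated; 2 ppm noise
           recovers > 99% of planted peaks", {
  db <- buildLipidDatabase(polarity = "positive", mzRange = c(400, 1000))
  ions <- ionsOf(db)
  set.seed(13)
  planted <- ions[sample(nrow(ions), 1000), ]
  # noise-free
  ann0 <- annotatePeaks(Spectrum(planted$mz[1:100], rep(1, 100)), db)
  found0 <- paste(planted$name[1:100], planted$adduct[1:100]) %in%
    paste(ann0$name, ann0$adduct)
  expect_true(all(found0))
  # 2 ppm Gaussian noise, 10 ppm window: P(miss) = P(|Z| > 5) ~ 6e-7
  noisy <- planted$mz * (1 + rnorm(1000, 0, 2) * 1e-6)
  ann <- annotatePeaks(Spectrum(noisy, rep(1, 1000)), db)
  found <- paste(planted$name, planted$adduct) %in%
    paste(ann$name, ann$adduct)
  expect_gt(mean(found), 0.99)
})

test_that("annotation is deterministic and idempotent", {
  db <- buildLipidDatabase(c("PC", "SM"), polarity = "positive")
  sp <- Spectrum(c(703.57, 760.58, 813.68), c(1, 2, 3))
  expect_identical(annotatePeaks(sp, db), annotatePeaks(sp, db))
})

test_that("MS/MS confirmation follows the class fragment rules", {
  db <- buildLipidDatabase("PC", cRange = c(34, 34), dRange = c(1, 1),
                           adducts = "[M+H]+")
  ann <- annotatePeaks(Spectrum(760.5851, 1), db)
  # phosphocholine head group present -> confirmed
  ms2 <- Spectrum(c(184.0733, 500.3), c(1e4, 10), msLevel = 2L,
                  precursorMz = 760.58)
  conf <- confirmWithMsms(ann, ms2)
  expect_true(all(conf$confirmed))
  # empty MS/MS -> unconfirmed
  empty2 <- Spectrum(numeric(), numeric(), msLevel = 2L, precursorMz = 760.58)
  expect_false(any(confirmWithMsms(ann, empty2)$confirmed))
  # precursor outside the 3 Da isolation window -> precondition violation
  far <- Spectrum(184.0733, 1, msLevel = 2L, precursorMz = 765.6)
  expect_error(confirmWithMsms(ann, far), "isolation window")
  # class without a positive-mode rule (PA) -> flagged no-rule
  dbpa <- buildLipidDatabase("PA", cRange = c(34, 34), dRange = c(1, 1),
                             adducts = "[M+H]+")
  annpa <- annotatePeaks(Spectrum(ionsOf(dbpa)$mz[1], 1), dbpa)
  ms2pa <- Spectrum(100.1, 1, msLevel = 2L,
                    precursorMz = ionsOf(dbpa)$mz[1])
  confpa <- confirmWithMsms(annpa, ms2pa)
  expect_false(any(confpa$confirmed))
  expect_identical(unique(confpa$confirm_note), "no-rule")
})

test_that("ambiguity resolution: confirmation tier, |ppm|, then name", {
  mk <- function(name, ppm, confirmed)
    data.frame(peak_mz = 700, intensity = 1, name = name, class = "PC",
               C = 34L, D = 1L, adduct = "[M+H]+", theoretical_mz = 700,
               ppm = ppm, confirmed = confirmed, stringsAsFactors = FALSE)
  both <- rbind(mk("PC 34:1", 1, FALSE), mk("SM 33:2", 3, TRUE))
  expect_identical(resolveAmbiguity(both)$name, "SM 33:2")
  one <- mk("PC 34:1", 2, NA)
  expect_identical(resolveAmbiguity(one)$name, "PC 34:1")
  tie <- rbind(mk("PE 35:1", 2, FALSE), mk("PC 34:1", 2, FALSE))
  expect_identical(resolveAmbiguity(tie)$name, "PC 34:1")
  expect_identical(resolveAmbiguity(tie), resolveAmbiguity(tie))
  expect_error(resolveAmbiguity(both[0, ]), "no candidates")
})

test_that("MGF files round-trip spectra", {
  sp <- list(
    A = Spectrum(c(184.0733, 500.25), c(1e4, 2e3), msLevel = 2L,
                 precursorMz = 760.5851),
    B = Spectrum(c(369.3516), c(5e3), polarity = "positive", msLevel = 2L,
                 precursorMz = 666.618))
  f <- tempfile(fileext = ".mgf")
  writeMgf(sp, f)
  back <- readMgf(f)
  expect_length(back, 2)
  expect_identical(names(back), c("A", "B"))
  expect_equal(peaksOf(back$A)$mz, peaksOf(sp$A)$mz, tolerance = 1e-6)
  expect_equal(back$A@precursorMz, 760.5851, tolerance = 1e-6)
})
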