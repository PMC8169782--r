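test_that("simulation is exactly reproducible from its seed", {
  a <- smallCohort(seed = 5)
  b <- smallCohort(seed = 5)
  expect_identical(intensityMatrix(a$features), intensityMatrix(b$features))
  expect_identical(trueFeatures(a$truth), trueFeatures(b$truth))
  c <- smallCohort(seed = 6)
  expect_false(identical(intensityMatrix(a$features),
                         intensityMatrix(c$features)))
})

test_that("a planted fold change materializes at the configured ratio", {
  mk <- data.frame(name = "PC 34:1", comparison = "control_vs_UF",
                   log2fc = 1, groups = "UF", stringsAsFactors = FALSE)
  # vanishing CV: group ratio must hit 2.0 essentially exactly
  cfg0 <- simulationConfig(groupSizes = c(control = 5L, UF = 5L, RUF = 2L),
                           nFeatures = 10L, markers = mk, cv = 1e-9,
                           seed = 2)
  sim0 <- simulateCohort(cfg0)
  fid <- plantedMarkers(sim0$truth)$feature_id
  g <- sampleGroups(sim0$features)
  x <- intensityMatrix(sim0$features)
  expect_equal(mean(x[fid, g == "UF"]) / mean(x[fid, g == "control"]),
               2.0, tolerance = 1e-6)
  # CV 0.3, n = 200/group: log-mean difference within its sampling CI
  cfg <- simulationConfig(groupSizes = c(control = 200L, UF = 200L,
                                         RUF = 2L),
                          nFeatures = 10L, markers = mk, cv = 0.3, seed = 2)
  sim <- simulateCohort(cfg)
  fid <- plantedMarkers(sim$truth)$feature_id
  g <- sampleGroups(sim$features)
  lx <- log10(intensityMatrix(sim$features))
  d <- mean(lx[fid, g == "UF"]) - mean(lx[fid, g == "control"])
  sigma10 <- sqrt(log(1 + 0.3^2)) / log(10)
  se <- sigma10 * sqrt(2 / 200)
  expect_lt(abs(d - log10(2)), 3.3 * se)
})

test_that("non-marker features are distributionally identical across groups", {
  cfg <- simulationConfig(groupSizes = c(control = 120L, UF = 120L,
                                         RUF = 2L),
                          nFeatures = 100L, seed = 21)
  sim <- simulateCohort(cfg)
  g <- sampleGroups(sim$features)
  lx <- log10(intensityMatrix(sim$features))
  # standardize per feature, then pool across features (~12 000 per group)
  z <- t(scale(t(lx[, g != "RUF"])))
  ks <- suppressWarnings(
    ks.test(as.numeric(z[, g[g != "RUF"] == "control"]),
            as.numeric(z[, g[g != "RUF"] == "UF"])))
  expect_gt(ks$p.value, 0.001)
})

test_that("the default study design matches the documented cohort", {
  cfg <- presetStudyDesign(seed = 1)
  expect_true(validObject(cfg, test = TRUE))
  expect_identical(cfg@groupSizes,
                   c(control = 15L, UF = 35L, RUF = 31L))
  expect_identical(cfg@nFeatures, 267L)
  mk <- cfg@markers
  expect_identical(sum(mk$comparison == "control_vs_UF"), 8L)
  expect_identical(sum(mk$comparison == "UF_vs_RUF"), 17L)
  expect_true(all(abs(mk$log2fc) >= 0.6 & abs(mk$log2fc) <= 1.5))
  expect_identical(cfg@cv, 0.3)
  expect_identical(cfg@mzRange, c(400, 1000))
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(simulationConfig(seed = 1, cv = -1), "cv must be > 0")
  expect_error(simulationConfig(seed = 1,
    groupSizes = c(control = 1L, UF = 5L, RUF = 5L)), "group sizes")
  expect_error(simulationConfig(), "seed is mandatory")
  mk <- data.frame(name = rep("PC 34:1", 5), comparison = "control_vs_UF",
                   log2fc = 1, groups = "UF")
  expect_error(simulationConfig(seed = 1, nFeatures = 3L, markers = mk),
               "more markers than features")
})

test_that("simulated spectra reflect the truth and respect the window", {
  sim <- smallCohort(seed = 9, nFeatures = 40)
  db <- buildLipidDatabase(polarity = "positive", mzRange = c(400, 1000))
  # noise-free m/z equals theoretical
  sp0 <- simulateSpectra(sim$truth, db, ppmSigma = 0)
  tf <- trueFeatures(sim$truth)
  expect_equal(sort(peaksOf(sp0$ms1)$mz),
               sort(tf$theoretical_mz[tf$theoretical_mz >= 400 &
                                      tf$theoretical_mz <= 1000]),
               tolerance = 1e-9)
  expect_true(all(peaksOf(sp0$ms1)$mz >= 400 & peaksOf(sp0$ms1)$mz <= 1000))
  # at 2 ppm noise, annotation recovers >= 99% of the planted species
  sp <- simulateSpectra(sim$truth, db, ppmSigma = 2)
  ann <- annotatePeaks(sp$ms1, db)
  rec <- paste(tf$name, tf$adduct) %in% paste(ann$name, ann$adduct)
  expect_gte(mean(rec), 0.99)
  # every MS/MS confirms its own class rule (when one exists)
  ann1 <- annotatePeaks(Spectrum(peaksOf(sp$msms[[1]])$mz * 0 +
                                 sp$msms[[1]]@precursorMz, 1), db)
  expect_true(nrow(ann1) >= 1)
})

test_that("spectra generation fails for species missing from the database", {
  sim <- smallCohort(seed = 9, nFeatures = 10)
  tiny <- buildLipidDatabase("LPC", polarity = "positive")
  expect_error(simulateSpectra(sim$truth, tiny), "not in database")
})
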