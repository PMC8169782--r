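.tinySet <- function() {
  x <- matrix(c(10, 20, 30, 40,
                 1,  2,  3,  4,
                 5,  0,  5, 10,
               100, 50, 25, 10,
                 8,  8,  8,  8), nrow = 5, byrow = TRUE)
  LipidFeatureSet(x,
    featureData = data.frame(feature_id = paste0("F", 1:5),
                             mz = c(500.1, 600.2, 700.3, 800.4, 900.5),
                             annotation = c("PC 34:1", "SM 40:1", NA,
                                            "TG 52:2", "LPC 18:2")),
    sampleData = data.frame(sample_id = c("c1", "c2", "u1", "u2"),
                            group = c("control", "control", "UF", "UF"),
                            matrix = "plasma", is_qc = FALSE))
}

test_that("feature tables round-trip losslessly through CSV", {
  fs <- .tinySet()
  tf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".csv")
  writeFeatureTable(fs, tf, sf)
  back <- readFeatureTable(tf, sf)
  expect_equal(intensityMatrix(back), intensityMatrix(fs))
  expect_identical(sampleGroups(back), sampleGroups(fs))
  expect_identical(featureAnnotations(back), featureAnnotations(fs))
  expect_equal(featureMz(back), featureMz(fs))
})

test_that("malformed tables are rejected with informative errors", {
  fs <- .tinySet()
  tf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".csv")
  writeFeatureTable(fs, tf, sf)
  tab <- read.csv(tf, check.names = FALSE)
  bad <- tab; bad$c1[2] <- -5
  bf <- tempfile(fileext = ".csv"); write.csv(bad, bf, row.names = FALSE)
  expect_error(readFeatureTable(bf, sf), "negative intensity.*F2")
  dup <- tab; dup$feature_id[2] <- "F1"
  df <- tempfile(fileext = ".csv"); write.csv(dup, df, row.names = FALSE)
  expect_error(readFeatureTable(df, sf), "duplicated feature id.*F1")
  short <- tab[, -ncol(tab)]
  mf <- tempfile(fileext = ".csv"); write.csv(short, mf, row.names = FALSE)
  expect_error(readFeatureTable(mf, sf), "do not match")
  expect_error(LipidFeatureSet(matrix(1, 2, 2),
    featureData = data.frame(feature_id = "F1", mz = 1, annotation = NA)),
    "do not match")
})

test_that("TIC normalization equalizes totals, preserves ratios, and is
           idempotent", {
  fs <- .tinySet()
  nf <- ticNormalize(fs)
  tot <- colSums(intensityMatrix(nf))
  expect_equal(unname(tot), rep(median(colSums(intensityMatrix(fs))), 4))
  # within-sample ratios preserved
  r0 <- intensityMatrix(fs)[1, ] / intensityMatrix(fs)[2, ]
  r1 <- intensityMatrix(nf)[1, ] / intensityMatrix(nf)[2, ]
  expect_equal(r1, r0)
  # already equal-sum table unchanged
  nf2 <- ticNormalize(nf)
  expect_equal(intensityMatrix(nf2), intensityMatrix(nf), tolerance = 1e-12)
  zero <- .tinySet()
  SummarizedExperiment::assay(zero, "intensity")[, 1] <- 0
  expect_error(ticNormalize(zero), "non-positive total")
})

test_that("QC RSD filter drops unstable features only", {
  x <- rbind(F1 = c(5, 5, 1, 1, 1),      # constant in QC -> kept
             F2 = c(5, 5, 1, 1, 10))     # QC RSD ~ 1.3 -> dropped
  fs <- LipidFeatureSet(x,
    featureData = data.frame(feature_id = c("F1", "F2"), mz = NA,
                             annotation = NA),
    sampleData = data.frame(sample_id = paste0("s", 1:5),
                            group = c("control", "UF", "QC", "QC", "QC"),
                            matrix = "plasma",
                            is_qc = c(FALSE, FALSE, TRUE, TRUE, TRUE)))
  kept <- qcRsdFilter(fs, maxRsd = 0.30)
  expect_identical(rownames(kept), "F1")
  # non-QC intensities untouched
  expect_equal(intensityMatrix(kept)["F1", ], intensityMatrix(fs)["F1", ])
  noqc <- .tinySet()
  expect_warning(out <- qcRsdFilter(noqc), "fewer than 3 QC")
  expect_equal(intensityMatrix(out), intensityMatrix(noqc))
})

test_that("half-minimum imputation follows the rule and drops dead rows", {
  x <- rbind(F1 = c(0, 4, 8), F2 = c(1, 2, 3), F3 = c(0, 0, 0))
  fs <- LipidFeatureSet(x,
    featureData = data.frame(feature_id = c("F1", "F2", "F3"), mz = NA,
                             annotation = NA),
    sampleData = data.frame(sample_id = paste0("s", 1:3),
                            group = "control", matrix = "plasma",
                            is_qc = FALSE))
  imp <- imputeHalfMin(fs)
  expect_identical(rownames(imp), c("F1", "F2"))
  expect_equal(unname(intensityMatrix(imp)["F1", ]), c(2, 4, 8))
  expect_equal(unname(intensityMatrix(imp)["F2", ]), c(1, 2, 3))
})

test_that("preprocessing preserves sample count and order", {
  sim <- smallCohort(seed = 3)
  fs <- sim$features
  out <- preprocess(fs)
  expect_identical(colnames(out), colnames(fs))
  expect_identical(sampleGroups(out), sampleGroups(fs))
  expect_identical(preprocess(fs), out)  # deterministic
})
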