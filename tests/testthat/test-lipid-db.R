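test_that("golden panel masses match the independent elemental oracle", {
  panel <- goldenPanel()
  for (i in seq_len(nrow(panel))) {
    comp <- lipidComposition(panel$class[i], panel$C[i], panel$D[i])
    expect_equal(formatFormula(comp), panel$formula[i],
                 info = paste(panel$class[i], panel$C[i], panel$D[i]))
    expect_lt(abs(monoisotopicMass(comp) - panel$mass[i]), 0.001)
  }
})

test_that("monoisotopic mass is an exact elemental sum", {
  expect_equal(monoisotopicMass(elementComposition(H = 2, O = 1)),
               18.010565, tolerance = 1e-6)
  expect_identical(monoisotopicMass(elementComposition()), 0)
  # SM d18:1/16:0 folded to SM 34:1
  expect_equal(monoisotopicMass(lipidComposition("SM", 34, 1)),
               702.5676, tolerance = 1e-4)
})

test_that("compositions reject invalid inputs", {
  expect_error(elementComposition(C = -1), "non-negative")
  expect_error(lipidComposition("XX", 34, 1), "unknown")
  expect_error(lipidComposition("PC", 10, 8), "D <= C/2")
  expect_error(lipidComposition("PC", 10, 1), "outside configured range")
})

test_that("database enumeration: counts, adduct arithmetic, determinism", {
  db <- buildLipidDatabase("PC", cRange = c(34, 34), dRange = c(0, 1),
                           adducts = "[M+H]+")
  expect_identical(nrow(ionsOf(db)), 2L)
  ion <- ionsOf(db)[ionsOf(db)$D == 1, ]
  expect_equal(ion$mz, 760.5851, tolerance = 1e-4)
  db2 <- buildLipidDatabase("PC", cRange = c(34, 34), dRange = c(0, 1),
                            adducts = "[M+H]+")
  expect_identical(db, db2)
  expect_error(buildLipidDatabase("FA", polarity = "positive"),
               "empty")
})

test_that("stored masses recompute from composition and the db is invariant
           under class-list permutation", {
  db1 <- buildLipidDatabase(c("PC", "SM", "TG"), polarity = "positive")
  db2 <- buildLipidDatabase(c("TG", "PC", "SM"), polarity = "positive")
  expect_identical(ionsOf(db1), ionsOf(db2))
  ions <- ionsOf(db1)
  take <- seq(1, nrow(ions), length.out = 50)
  for (i in round(take)) {
    m <- monoisotopicMass(lipidComposition(ions$class[i], ions$C[i],
                                           ions$D[i]))
    expect_lt(abs(m - ions$mass[i]), 1e-6)
  }
})

test_that("ppm error: sign, magnitude, boundary, domain", {
  expect_identical(ppmError(760.5851, 760.5851), 0)
  expect_equal(ppmError(760.5927, 760.5851), 10.0, tolerance = 0.01)
  expect_equal(ppmError(0, 760.5851), -1e6)
  expect_error(ppmError(500, 0), "must be > 0")
})

test_that("window query equals a brute-force linear scan", {
  db <- buildLipidDatabase(c("PC", "SM"), polarity = "positive")
  ions <- ionsOf(db)
  set.seed(42)
  queries <- c(sample(ions$mz, 500) * (1 + runif(500, -15, 15) * 1e-6),
               runif(500, 400, 1100))
  for (mz in queries) {
    got <- queryMz(db, mz, tolPpm = 10)
    ref <- ions[abs(ppmError(mz, ions$mz)) <= 10, , drop = FALSE]
    expect_setequal(paste(got$name, got$adduct),
                    paste(ref$name, ref$adduct))
    if (nrow(got) > 1)
      expect_true(!is.unsorted(abs(got$ppm)))
  }
})

test_that("query edge behaviour: exact hit first, outside window empty", {
  db <- buildLipidDatabase("PC", cRange = c(34, 34), dRange = c(1, 1),
                           adducts = "[M+H]+")
  mz0 <- ionsOf(db)$mz[1]
  hit <- queryMz(db, mz0)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$ppm, 0)
  expect_identical(nrow(queryMz(db, mz0 * (1 + 10.5e-6))), 0L)
})

test_that("database round-trips through TSV and JSON", {
  db <- buildLipidDatabase("LPC", polarity = "positive")
  tsv <- tempfile(fileext = ".tsv"); json <- tempfile(fileext = ".json")
  writeLipidDatabase(db, tsv, "tsv")
  writeLipidDatabase(db, json, "json")
  expect_equal(ionsOf(readLipidDatabase(tsv, "tsv"))$mz, ionsOf(db)$mz,
               tolerance = 1e-9)
  expect_equal(ionsOf(readLipidDatabase(json, "json"))$name,
               ionsOf(db)$name)
})

test_that("lipid names parse, sum chains, and round-trip", {
  p <- parseLipidName(c("PC 34:1", "PC 16:0_20:3", "SM d18:1/22:0",
                        "TG 18:0_18:1_18:1", "CE 18:2"))
  expect_identical(p$class, c("PC", "PC", "SM", "TG", "CE"))
  expect_identical(p$C, c(34L, 36L, 40L, 54L, 18L))
  expect_identical(p$D, c(1L, 3L, 1L, 2L, 2L))
  # canonical names round-trip for every class
  for (cls in lipidClassCodes()) {
    nm <- lipidName(cls, 36, 2)
    q <- parseLipidName(nm)
    expect_identical(c(q$class, q$C, q$D), c(cls, 36L, 2L))
  }
  expect_error(parseLipidName("PC thirty:four"), "cannot parse")
  expect_identical(lipidChains("PC 16:0_18:2"), c("16:0", "18:2"))
  expect_identical(lipidChains("SM d18:1/22:0"), c("18:1", "22:0"))
  expect_identical(lipidChains("PC 34:1"), character())
})
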