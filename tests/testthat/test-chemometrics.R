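.sepData <- function(seed = 4, n = 24, p = 8, shift = 3) {
  # well-separated two-class data: strong signal in the first 2 features
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + shift * y
    X[, 2] <- X[, 2] - shift * y
    colnames(X) <- paste0("V", seq_len(p))
    list(X = X, y = y)
  })
}

test_that("a perfect single predictor gives R2Y = 1", {
  y <- rep(c(0, 1), each = 6)
  X <- cbind(pred = y)
  m <- fitOpls(X, y, nOrtho = 0, folds = 4)
  expect_equal(m@R2Y, 1.0, tolerance = 1e-12)
})

test_that("with no orthogonal components the predictive component equals
           an independent NIPALS PLS1 first component", {
  withr::with_seed(77, {
    X <- matrix(rnorm(60), 10, 6)
    y <- rep(c(0, 1), each = 5)
  })
  m <- fitOpls(X, y, nOrtho = 0, folds = 5)
  sc <- list(center = m@scaling$center, scale = m@scaling$scale)
  Xs <- scale(X[, m@scaling$keep, drop = FALSE], sc$center, sc$scale)
  ref <- nipalsPls1(Xs, y - mean(y))
  s <- sign(sum(ref$w * m@weights))  # component sign is a convention
  expect_equal(s * ref$w, unname(m@weights), tolerance = 1e-8)
  expect_equal(s * ref$t, unname(m@scores), tolerance = 1e-8)
  expect_equal(s * ref$p, unname(m@loadings), tolerance = 1e-8)
})

test_that("orthogonal scores are uncorrelated with y and VIP squares sum
           to the feature count on every fitted model", {
  for (seed in c(4, 5, 6)) {
    d <- .sepData(seed)
    m <- fitOpls(d$X, d$y, nOrtho = 2, folds = 4, seed = seed)
    yc <- d$y - mean(d$y)
    for (k in seq_len(m@nOrtho))
      expect_lt(abs(cor(m@orthoScores[, k], yc)), 1e-8)
    expect_equal(sum(m@vip^2), length(m@vip), tolerance = 1e-6)
    expect_lte(m@Q2Y, m@R2Y + 1e-6)
    expect_true(m@R2X >= 0 && m@R2X <= 1)
  }
})

test_that("scores and loadings reconstruct scaled X up to the R2X residual", {
  d <- .sepData(9)
  m <- fitOpls(d$X, d$y, nOrtho = 1, folds = 4, seed = 9)
  Xs <- scale(d$X[, m@scaling$keep], m@scaling$center, m@scaling$scale)
  modeled <- tcrossprod(m@scores, m@loadings) +
    m@orthoScores %*% t(m@orthoLoadings)
  r2x <- 1 - sum((Xs - modeled)^2) / sum(Xs^2)
  expect_equal(r2x, m@R2X, tolerance = 1e-10)
})

test_that("symmetric weights give unit VIP everywhere; a dominant
           predictor attains the maximum VIP", {
  y <- rep(c(0, 1), each = 8)
  base <- withr::with_seed(2, rnorm(16))
  X <- cbind(a = base + y, b = -(base + y))  # equal |w|
  m <- fitOpls(X, y, nOrtho = 0, folds = 4)
  expect_equal(unname(m@vip), c(1, 1), tolerance = 1e-10)
  d <- .sepData(11, shift = 4)
  X2 <- d$X; X2[, 2] <- withr::with_seed(3, rnorm(nrow(X2)))  # one signal col
  m2 <- fitOpls(X2, d$y, nOrtho = 1, folds = 4)
  expect_identical(names(which.max(m2@vip)), "V1")
  expect_identical(selectMarkers(m2, threshold = max(m2@vip)), character())
  expect_setequal(selectMarkers(m2, threshold = 0), names(m2@vip))
})

test_that("cross-validated Q2: high for near-noiseless separable data,
           null-centered for permuted labels, reproducible", {
  # essentially deterministic class difference -> Q2 close to 1
  withr::with_seed(21, {
    y <- rep(c(0, 1), each = 15)
    X <- cbind(a = 4 * y + rnorm(30, 0, 0.05),
               b = -2 * y + rnorm(30, 0, 0.05),
               c = rnorm(30, 0, 0.05))
  })
  q2 <- crossValidatedQ2(X, y, folds = 7, seed = 1)
  expect_gt(q2, 0.9)
  expect_identical(crossValidatedQ2(X, y, folds = 7, seed = 1), q2)
  # permutation null centers near zero once n dominates the model size
  withr::with_seed(5, {
    yb <- rep(c(0, 1), each = 75)
    Xb <- matrix(rnorm(150 * 10), 150, 10)
    q2null <- replicate(30,
      crossValidatedQ2(Xb, sample(yb), folds = 7, seed = 1))
  })
  expect_lt(abs(mean(q2null)), 0.15)
  expect_error(crossValidatedQ2(X, y, folds = 1), "folds")
})

test_that("the model is invariant to sample order (up to component sign)", {
  d <- .sepData(33)
  m1 <- fitOpls(d$X, d$y, nOrtho = 1, folds = 4, seed = 2)
  perm <- withr::with_seed(6, sample(nrow(d$X)))
  m2 <- fitOpls(d$X[perm, ], d$y[perm], nOrtho = 1, folds = 4, seed = 2)
  expect_equal(m2@R2Y, m1@R2Y, tolerance = 1e-10)
  expect_equal(m2@R2X, m1@R2X, tolerance = 1e-10)
  expect_equal(m2@vip, m1@vip, tolerance = 1e-10)
  # sign convention: class 1 has positive mean predictive score
  expect_gt(mean(m1@scores[d$y == 1]), 0)
  expect_gt(mean(m2@scores[d$y[perm] == 1]), 0)
})

test_that("permutation validation ranks a real signal first and is
           reproducible", {
  d <- .sepData(40, n = 24, shift = 4)
  pv <- permutationValidation(d$X, d$y, nPerm = 24, seed = 3, folds = 4)
  expect_lte(pv$pQ2, 1 / 25)
  expect_gt(pv$observedQ2Y, max(pv$q2y))
  pv2 <- permutationValidation(d$X, d$y, nPerm = 24, seed = 3, folds = 4)
  expect_identical(pv$q2y, pv2$q2y)
  expect_error(permutationValidation(d$X, d$y, nPerm = 5), ">= 20")
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fitOpls(X, rep(0, 10)), "two classes")
  expect_error(fitOpls(matrix(1, 10, 2), rep(c(0, 1), 5)), "zero variance")
  expect_error(fitOpls(X[1:5, ], c(0, 0, 1, 1, 1)), "at least 3")
})
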