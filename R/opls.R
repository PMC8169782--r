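# OPLS-DA from first principles: a single predictive latent component
# plus y-orthogonal components removed from X beforehand, cross-validated
# Q2Y, per-feature VIP scores and permutation validation. Two-class only
# (the discriminant setting): y is coded 0/1 and centered, X is centered
# and scaled (unit variance by default, pareto available).

.makeScaling <- function(X, mode = c("uv", "pareto", "none"), center = TRUE) {
  mode <- match.arg(mode)
  v <- apply(X, 2, stats::var)
  keep <- v > .Machine$double.eps
  ctr <- if (center) colMeans(X[, keep, drop = FALSE]) else
    rep(0, sum(keep))
  scl <- switch(mode,
    uv = sqrt(v[keep]),
    pareto = sqrt(sqrt(v[keep])),
    none = rep(1, sum(keep)))
  list(center = ctr, scale = scl, mode = mode, keep = which(keep))
}

.applyScaling <- function(X, sc) {
  X <- X[, sc$keep, drop = FALSE]
  sweep(sweep(X, 2, sc$center, `-`), 2, sc$scale, `/`)
}

.codeY <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2) stop("y must have exactly two classes")
  list(num = as.numeric(f) - 1, levels = levels(f))
}

# core decomposition on an already scaled X and centered y; returns the
# component system without summaries
.oplsCore <- function(Xs, yc, nOrtho) {
  p <- ncol(Xs)
  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  Wo <- matrix(0, p, nOrtho); Po <- matrix(0, p, nOrtho)
  To <- matrix(0, nrow(Xs), nOrtho)
  Xf <- Xs
  k <- 0L
  while (k < nOrtho) {
    t <- drop(Xf %*% w)
    pv <- drop(crossprod(Xf, t)) / sum(t^2)
    wo <- pv - drop(crossprod(w, pv)) * w    # part of p orthogonal to w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break                   # no orthogonal variation left
    wo <- wo / nrm
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    k <- k + 1L
    Wo[, k] <- wo; Po[, k] <- po; To[, k] <- to
    Xf <- Xf - tcrossprod(to, po)
  }
  Wo <- Wo[, seq_len(k), drop = FALSE]
  Po <- Po[, seq_len(k), drop = FALSE]
  To <- To[, seq_len(k), drop = FALSE]
  t <- drop(Xf %*% w)
  pv <- drop(crossprod(Xf, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  list(w = w, t = t, p = pv, q = q, Wo = Wo, Po = Po, To = To, Xf = Xf,
       nOrtho = k)
}

# project new (already scaled) samples through a fitted core
.oplsProject <- function(core, Xs) {
  Xf <- Xs
  for (k in seq_len(core$nOrtho)) {
    to <- drop(Xf %*% core$Wo[, k])
    Xf <- Xf - tcrossprod(to, core$Po[, k])
  }
  drop(Xf %*% core$w) * core$q
}

.stratifiedFolds <- function(y, k, seed) {
  withSeed(as.integer(seed), {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit an OPLS-DA model
#'
#' Codes the two classes 0/1 and centers the response; centers and
#' scales X; strips \code{nOrtho} y-orthogonal components from X
#' (orthogonal scores are uncorrelated with y by construction); fits the
#' predictive component on the filtered X. The sign of the predictive
#' component is fixed so the class coded 1 has a positive mean score.
#' R2X is the fraction of scaled-X variance captured by all modeled
#' components; R2Y the fraction of y variance explained in training;
#' Q2Y the cross-validated counterpart (stratified folds, scaling
#' re-estimated inside every training split).
#'
#' @param X numeric matrix, samples x features
#' @param y two-class vector (factor, character or 0/1); the second
#'   factor level is coded 1
#' @param nOrtho number of orthogonal components (default 1)
#' @param scaling "uv" (unit variance, default), "pareto" or "none"
#' @param folds cross-validation folds for Q2Y (default 7; set to the
#'   sample count for leave-one-out)
#' @param seed seed for fold assignment
#' @return an \linkS4class{OplsModel}
#' @export
fitOpls <- function(X, y, nOrtho = 1L, scaling = "uv", folds = 7L,
                    seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  yy <- .codeY(y)
  if (min(table(yy$num)) < 3) stop("each class needs at least 3 samples")
  sc <- .makeScaling(X, scaling)
  if (!length(sc$keep)) stop("all features have zero variance")
  Xs <- .applyScaling(X, sc)
  yc <- yy$num - mean(yy$num)
  core <- .oplsCore(Xs, yc, as.integer(nOrtho))
  # sign convention: class 1 scores positive
  if (mean(core$t[yy$num == 1]) < 0) {
    core$w <- -core$w; core$t <- -core$t; core$p <- -core$p
    core$q <- -core$q
  }
  ssX <- sum(Xs^2)
  modeled <- tcrossprod(core$t, core$p)
  if (core$nOrtho > 0) modeled <- modeled + core$To %*% t(core$Po)
  R2X <- 1 - sum((Xs - modeled)^2) / ssX
  yhat <- core$t * core$q
  R2Y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  # VIP over the predictive component: with one component the SSY
  # weights cancel and VIP_j = sqrt(p) |w_j| / ||w||
  nf <- length(core$w)
  vip <- sqrt(nf) * abs(core$w) / sqrt(sum(core$w^2))
  names(vip) <- colnames(X)[sc$keep]
  Q2 <- crossValidatedQ2(X, y, nOrtho = nOrtho, folds = folds, seed = seed,
                         scaling = scaling)
  new("OplsModel", weights = core$w, loadings = core$p, scores = core$t,
      yLoading = core$q, orthoWeights = core$Wo, orthoLoadings = core$Po,
      orthoScores = core$To, R2X = R2X, R2Y = R2Y, Q2Y = Q2, vip = vip,
      scaling = sc, yLevels = yy$levels, yMean = mean(yy$num),
      nOrtho = core$nOrtho, folds = as.integer(folds),
      seed = as.integer(seed))
}

#' Cross-validated Q2Y of an OPLS-DA model
#'
#' Stratified k-fold cross-validation: the scaling and the full
#' component system are re-estimated inside every training split, the
#' held-out samples are projected, and
#' Q2 = 1 - PRESS / SS(y centered) accumulates the held-out squared
#' prediction errors.
#'
#' @inheritParams fitOpls
#' @return Q2Y (can be negative when the model predicts worse than the
#'   mean)
#' @export
crossValidatedQ2 <- function(X, y, nOrtho = 1L, folds = 7L, seed = 1L,
                             scaling = "uv") {
  X <- as.matrix(X)
  yy <- .codeY(y)
  n <- length(yy$num)
  folds <- as.integer(folds)
  if (folds < 2 || folds > n) stop("folds must be in [2, n]")
  fold <- .stratifiedFolds(yy$num, folds, seed)
  press <- 0
  for (f in sort(unique(fold))) {
    te <- which(fold == f); tr <- which(fold != f)
    if (length(unique(yy$num[tr])) < 2)
      stop("a training split lost a class; reduce folds")
    sc <- .makeScaling(X[tr, , drop = FALSE], scaling)
    if (!length(sc$keep)) stop("all features have zero variance in a fold")
    Xtr <- .applyScaling(X[tr, , drop = FALSE], sc)
    ymu <- mean(yy$num[tr])
    core <- .oplsCore(Xtr, yy$num[tr] - ymu, as.integer(nOrtho))
    Xte <- .applyScaling(X[te, , drop = FALSE], sc)
    pred <- .oplsProject(core, Xte) + ymu
    press <- press + sum((yy$num[te] - pred)^2)
  }
  1 - press / sum((yy$num - mean(yy$num))^2)
}

#' @describeIn fitOpls per-feature variable importance in projection;
#'   squares sum to the number of modeled features.
#' @param model a fitted \linkS4class{OplsModel}
#' @export
setMethod("vipScores", "OplsModel", function(model) model@vip)

#' @describeIn fitOpls feature names with VIP strictly above the
#'   threshold, sorted by decreasing VIP.
#' @param threshold VIP cutoff (default 1.0, strict inequality)
#' @export
setMethod("selectMarkers", "OplsModel", function(model, threshold = 1.0) {
  v <- sort(model@vip, decreasing = TRUE)
  names(v)[v > threshold]
})

#' Predict OPLS-DA scores and responses for new samples
#'
#' @param model a fitted \linkS4class{OplsModel}
#' @param newdata numeric matrix, samples x features (original feature
#'   space and order)
#' @return list with predictive scores \code{t} and continuous response
#'   predictions \code{yhat} (on the 0/1 coding scale)
#' @export
predictOpls <- function(model, newdata) {
  Xs <- .applyScaling(as.matrix(newdata), model@scaling)
  core <- list(w = model@weights, q = model@yLoading,
               Wo = model@orthoWeights, Po = model@orthoLoadings,
               nOrtho = model@nOrtho)
  Xf <- Xs
  for (k in seq_len(core$nOrtho)) {
    to <- drop(Xf %*% core$Wo[, k])
    Xf <- Xf - tcrossprod(to, core$Po[, k])
  }
  t <- drop(Xf %*% core$w)
  list(t = t, yhat = t * core$q + model@yMean)
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model on label-permuted responses and reports the null
#' distributions of R2Y and Q2Y together with the empirical p-value of
#' the observed Q2Y (rank-based, with the +1 correction).
#'
#' @inheritParams fitOpls
#' @param nPerm number of permutations (>= 20)
#' @return list: \code{r2y}, \code{q2y} (null vectors),
#'   \code{observedR2Y}, \code{observedQ2Y}, \code{pQ2}
#' @export
permutationValidation <- function(X, y, nPerm = 100L, seed = 1L,
                                  nOrtho = 1L, folds = 7L, scaling = "uv") {
  if (nPerm < 20) stop("nPerm must be >= 20")
  X <- as.matrix(X)
  yy <- .codeY(y)
  obs <- fitOpls(X, y, nOrtho = nOrtho, scaling = scaling, folds = folds,
                 seed = seed)
  perms <- withSeed(as.integer(seed) + 1L,
    lapply(seq_len(nPerm), function(i) sample(yy$num)))
  r2 <- q2 <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    m <- fitOpls(X, perms[[i]], nOrtho = nOrtho, scaling = scaling,
                 folds = folds, seed = seed + i)
    r2[i] <- m@R2Y; q2[i] <- m@Q2Y
  }
  list(r2y = r2, q2y = q2, observedR2Y = obs@R2Y, observedQ2Y = obs@Q2Y,
       pQ2 = (1 + sum(q2 >= obs@Q2Y)) / (nPerm + 1))
}

setMethod("show", "OplsModel", function(object) {
  cat(sprintf(
    "OplsModel: 1 predictive + %d orthogonal component(s), %d features\n",
    object@nOrtho, length(object@vip)))
  cat(sprintf("  classes: %s (0) vs %s (1)\n",
              object@yLevels[1], object@yLevels[2]))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2Y = %.3f (%d-fold CV)\n",
              object@R2X, object@R2Y, object@Q2Y, object@folds))
  cat("  features with VIP > 1:", sum(object@vip > 1), "\n")
})

#' Export an OPLS-DA model summary
#'
#' @param model a fitted \linkS4class{OplsModel}
#' @param scoresPath optional TSV path for the score table (sample,
#'   predictive score, orthogonal scores)
#' @return list (invisibly written as JSON when \code{jsonPath} given)
#'   with R2X/R2Y/Q2Y, component counts and the VIP table
#' @param jsonPath optional JSON output path
#' @export
oplsSummary <- function(model, jsonPath = NULL, scoresPath = NULL) {
  s <- list(R2X = model@R2X, R2Y = model@R2Y, Q2Y = model@Q2Y,
            nOrtho = model@nOrtho, folds = model@folds,
            classes = model@yLevels,
            vip = data.frame(feature = names(model@vip),
                             vip = unname(model@vip)))
  if (!is.null(jsonPath))
    jsonlite::write_json(s, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(scoresPath)) {
    tab <- data.frame(sample = seq_along(model@scores), t = model@scores)
    if (model@nOrtho > 0)
      tab <- cbind(tab, stats::setNames(
        as.data.frame(model@orthoScores),
        sprintf("to%d", seq_len(model@nOrtho))))
    utils::write.table(tab, scoresPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(s)
}
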