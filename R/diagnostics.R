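# Logistic diagnostic models on marker panels:
# y = 1 / (1 + exp(-(b0 + b . I))) over raw marker intensities, fitted
# by iteratively reweighted least squares with a tiny ridge on the
# (internally standardized) slopes for stability under the
# quasi-separation that VIP pre-selection often induces, with
# leave-one-out sensitivity/specificity.

#' Fit a logistic diagnostic model
#'
#' Maximum-likelihood logistic regression via IRLS. Predictors enter on
#' their raw intensity scale; internally columns are standardized for
#' conditioning and a small ridge \code{ridgeLambda} is applied to the
#' standardized slopes (not the intercept), then coefficients are mapped
#' back. Wald z statistics, p-values and 95 percent confidence
#' intervals are reported per coefficient. Complete separation is
#' detected (perfectly classified training data with diverging linear
#' predictors) and flagged rather than treated as an error.
#'
#' @param X numeric matrix, samples x markers (raw intensities)
#' @param y two-class response; second factor level is coded 1
#' @param ridgeLambda ridge penalty on standardized slopes (default 1e-8)
#' @param maxIter,tol IRLS iteration cap and relative deviance tolerance
#' @return a \linkS4class{LogisticModel}
#' @export
fitLogisticPanel <- function(X, y, ridgeLambda = 1e-8, maxIter = 100L,
                             tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("M%d", seq_len(ncol(X)))
  yy <- .codeY(y)
  yb <- yy$num
  n <- nrow(X); p <- ncol(X)
  if (n != length(yb)) stop("X rows must match length(y)")
  if (n <= p)
    warning("more markers than samples minus one; estimates are unstable")
  # standardize for conditioning; constant columns get scale 1
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- cbind(`(Intercept)` = 1, sweep(sweep(X, 2, ctr, `-`), 2, scl, `/`))
  pen <- diag(c(0, rep(ridgeLambda, p)), p + 1)
  beta <- numeric(p + 1)
  dev <- Inf; converged <- FALSE; it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (yb - mu) / w
    fit <- solve(crossprod(Z, Z * w) + pen, crossprod(Z, w * z))
    beta <- drop(fit)
    newdev <- -2 * sum(yb * stats::plogis(drop(Z %*% beta), log.p = TRUE) +
                       (1 - yb) * stats::plogis(-drop(Z %*% beta),
                                                log.p = TRUE))
    if (is.finite(dev) && abs(dev - newdev) / (abs(newdev) + 0.1) < tol) {
      converged <- TRUE; dev <- newdev; break
    }
    dev <- newdev
  }
  eta <- drop(Z %*% beta)
  separation <- all((eta > 0) == (yb == 1)) && max(abs(eta)) > 15
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  V <- solve(crossprod(Z, Z * w) + pen)
  # back-transform to the raw intensity scale
  A <- diag(c(1, 1 / scl), p + 1)
  A[1, -1] <- -ctr / scl
  bRaw <- drop(A %*% beta)
  Vraw <- A %*% V %*% t(A)
  se <- sqrt(pmax(diag(Vraw), 0))
  zstat <- ifelse(se > 0, bRaw / se, NA_real_)
  pval <- 2 * stats::pnorm(-abs(zstat))
  ci <- cbind(lower = bRaw - 1.959964 * se, upper = bRaw + 1.959964 * se)
  nm <- c("(Intercept)", colnames(X))
  names(bRaw) <- names(se) <- names(zstat) <- names(pval) <- nm
  rownames(ci) <- nm
  new("LogisticModel", coefficients = bRaw, se = se, z = zstat, p = pval,
      ci = ci, converged = converged, iterations = it,
      separation = separation, ridgeLambda = ridgeLambda,
      yLevels = yy$levels)
}

#' Predicted class-1 probability
#'
#' Evaluates y = 1 / (1 + exp(-(b0 + b . I))) for new marker intensity
#' vectors; numerically stable over the full double range of the linear
#' predictor.
#'
#' @param model a \linkS4class{LogisticModel}
#' @param newdata numeric vector (one sample) or matrix (samples x
#'   markers), columns in model coefficient order
#' @return probabilities in (0, 1)
#' @export
setMethod("predictProb", "LogisticModel", function(model, newdata) {
  b <- model@coefficients
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(b) - 1L)
    stop("newdata has ", ncol(newdata), " markers; model expects ",
         length(b) - 1L)
  drop(stats::plogis(b[1] + as.matrix(newdata) %*% b[-1]))
})

setMethod("show", "LogisticModel", function(object) {
  cat(sprintf("LogisticModel: %d markers, %s (0) vs %s (1)\n",
              length(object@coefficients) - 1L,
              object@yLevels[1], object@yLevels[2]))
  cat(sprintf("  converged: %s (%d IRLS iterations)%s\n",
              object@converged, object@iterations,
              if (object@separation) " [complete separation detected]"
              else ""))
  print(data.frame(beta = object@coefficients, se = object@se,
                   z = object@z, p = object@p))
})

#' Coefficient table of a logistic model
#' @param model a \linkS4class{LogisticModel}
#' @return data.frame: term, beta, ci_lower, ci_upper, z, p
#' @export
coefficientTable <- function(model) {
  data.frame(term = names(model@coefficients),
             beta = unname(model@coefficients),
             ci_lower = unname(model@ci[, "lower"]),
             ci_upper = unname(model@ci[, "upper"]),
             z = unname(model@z), p = unname(model@p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Leave-one-out diagnostic performance
#'
#' For every sample the model is refitted on the remaining n - 1 and
#' the held-out sample is classified as class 1 when its predicted
#' probability reaches \code{threshold}. A training fold reduced to a
#' single class is flagged, its sample excluded from the counts, and a
#' warning emitted.
#'
#' @param X numeric matrix, samples x markers (raw intensities)
#' @param y two-class response (second level coded 1)
#' @param threshold classification threshold (default 0.5)
#' @param ridgeLambda passed to [fitLogisticPanel()]
#' @return a \linkS4class{DiagnosticPerformance}
#' @export
loocvPerformance <- function(X, y, threshold = 0.5, ridgeLambda = 1e-8) {
  X <- as.matrix(X)
  yy <- .codeY(y)
  yb <- yy$num
  n <- nrow(X)
  if (n < 6 || min(table(yb)) < 3)
    stop("need n >= 6 with at least 3 samples per class")
  tp <- fp <- tn <- fn <- excl <- 0L
  for (i in seq_len(n)) {
    ytr <- yb[-i]
    if (length(unique(ytr)) < 2) { excl <- excl + 1L; next }
    m <- suppressWarnings(
      fitLogisticPanel(X[-i, , drop = FALSE], ytr,
                       ridgeLambda = ridgeLambda))
    pr <- predictProb(m, X[i, , drop = FALSE])
    call1 <- pr >= threshold
    if (yb[i] == 1) { if (call1) tp <- tp + 1L else fn <- fn + 1L }
    else            { if (call1) fp <- fp + 1L else tn <- tn + 1L }
  }
  if (excl > 0) warning(excl, " sample(s) excluded: training fold lost a class")
  new("DiagnosticPerformance", tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
      threshold = threshold, excluded = excl)
}

setMethod("show", "DiagnosticPerformance", function(object) {
  cat(sprintf(
    "DiagnosticPerformance (LOOCV, threshold %.2f):\n", object@threshold))
  cat(sprintf("  sensitivity = %.3f  specificity = %.3f\n",
              object@sensitivity, object@specificity))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d (excluded: %d)\n",
              object@tp, object@fp, object@tn, object@fn, object@excluded))
})
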