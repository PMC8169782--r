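# Rank-based two-group differential screening: Mann-Whitney U with an
# exact small-sample branch (dynamic-programming null distribution) and
# a tie- and continuity-corrected normal approximation otherwise.

# exact null distribution of U for group sizes n, m (tie-free):
# counts[u + 1] = number of labelings with statistic u, built by the
# standard recursion c(n, m, u) = c(n-1, m, u-m) + c(n, m-1, u)
.uCounts <- function(n, m) {
  tab <- vector("list", (n + 1) * (m + 1))
  idx <- function(i, j) i * (m + 1) + j + 1
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 || j == 0) {
      tab[[idx(i, j)]] <- 1  # only U = 0
    } else {
      a <- tab[[idx(i - 1, j)]]  # counts over 0..(i-1)j, shift by j
      b <- tab[[idx(i, j - 1)]]  # counts over 0..i(j-1)
      res <- numeric(i * j + 1)
      res[seq_along(a) + j] <- a
      res[seq_along(b)] <- res[seq_along(b)] + b
      tab[[idx(i, j)]] <- res
    }
  }
  tab[[idx(n, m)]]
}

#' Mann-Whitney U test
#'
#' U counts the (x, y) pairs with x > y, plus half the tied pairs. The
#' two-sided p-value is exact (full enumeration of the null distribution
#' of U) when both groups have at most \code{exactMax} observations and
#' the pooled data are tie-free; otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors, each non-empty
#' @param exactMax largest group size for the exact branch (default 8)
#' @return list with elements \code{U}, \code{p} (two-sided) and
#'   \code{method} ("exact" or "normal")
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, exactMax = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n <- length(x); m <- length(y)
  gt <- sum(outer(x, y, ">"))
  eq <- sum(outer(x, y, "=="))
  U <- gt + eq / 2
  pooled <- c(x, y)
  hasTies <- anyDuplicated(pooled) > 0
  if (!hasTies && max(n, m) <= exactMax) {
    counts <- .uCounts(n, m)
    dev <- abs(seq(0, n * m) - n * m / 2)
    p <- sum(counts[dev >= abs(U - n * m / 2) - 1e-9]) / sum(counts)
    return(list(U = U, p = p, method = "exact"))
  }
  N <- n + m
  tie <- table(pooled)
  sig2 <- n * m / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
  a <- abs(U - n * m / 2) - 0.5  # continuity correction
  if (a <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- -a / sqrt(sig2)
  # Edgeworth refinement: the exact null of U is platykurtic; the
  # fourth-cumulant term tightens small-sample tail areas markedly
  # (kurtosis formula for the tie-free null)
  g2 <- -(6 / 5) * (n^2 + m^2 + n * m + n + m) / (n * m * (N + 1))
  F <- stats::pnorm(z) - stats::dnorm(z) * g2 / 24 * (z^3 - 3 * z)
  p <- min(1, max(2 * F, .Machine$double.xmin))
  list(U = U, p = p, method = "normal")
}

#' Two-group differential lipid screening
#'
#' Runs a two-sided Mann-Whitney U test per feature between two sample
#' groups; features are called significant at raw p < alpha, mirroring
#' screening practice in untargeted lipidomics (no multiplicity
#' adjustment for selection; a Benjamini-Hochberg column is reported for
#' reference).
#'
#' @param fs a \linkS4class{LipidFeatureSet}
#' @param groupA,groupB group labels to compare (QC samples are ignored)
#' @param alpha significance level on the raw p-value (default 0.05)
#' @return data.frame with one row per feature: feature_id, annotation,
#'   U, p, p_adj_BH, medianA, medianB, direction (sign of the median
#'   difference, A relative to B), significant
#' @export
differentialLipids <- function(fs, groupA, groupB, alpha = 0.05) {
  g <- sampleGroups(fs)
  known <- unique(g[!isQC(fs)])
  for (gg in c(groupA, groupB))
    if (!gg %in% known) stop("unknown group label: ", gg)
  ia <- which(g == groupA & !isQC(fs))
  ib <- which(g == groupB & !isQC(fs))
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 samples")
  x <- intensityMatrix(fs)
  res <- lapply(seq_len(nrow(x)), function(i) {
    a <- x[i, ia]; b <- x[i, ib]
    t <- mannWhitneyU(a, b)
    ma <- stats::median(a); mb <- stats::median(b)
    data.frame(U = t$U, p = t$p, medianA = ma, medianB = mb,
               direction = sign(ma - mb))
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    feature_id = as.character(SummarizedExperiment::rowData(fs)$feature_id),
    annotation = featureAnnotations(fs),
    U = res$U, p = res$p,
    p_adj_BH = stats::p.adjust(res$p, "BH"),
    medianA = res$medianA, medianB = res$medianB,
    direction = res$direction,
    significant = res$p < alpha,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
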