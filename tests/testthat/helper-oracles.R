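# Independent oracles used to cross-check the implementation. Each is a
# deliberately different route to the same quantity: brute-force
# enumeration, a textbook NIPALS loop, and combinatorial identities.

# --- golden lipid panel -------------------------------------------------
# 20 species across all supported classes; formulas and monoisotopic
# masses precomputed with an independent elemental-mass calculator
# (pyteomics.mass over the same composition rules) and frozen here.
goldenPanel <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = '
class  C  D  formula      mass
PC     34 1  C42H82NO8P   759.577805
PC     36 2  C44H84NO8P   785.593455
PC     38 4  C46H84NO8P   809.593455
LPC    18 2  C26H50NO7P   519.332490
LPC    16 0  C24H50NO7P   495.332490
PE     34 1  C39H76NO8P   717.530855
PE     36 4  C41H74NO8P   739.515205
PS     38 3  C44H80NO10P  813.551984
PS     40 3  C46H84NO10P  841.583285
PA     44 5  C47H83O8P    806.582556
PC-O   34 1  C42H84NO7P   745.598541
PE-O   36 2  C41H80NO7P   729.567241
SM     34 1  C39H79N2O6P  702.567575
SM     40 1  C45H91N2O6P  786.661475
SM     42 2  C47H93N2O6P  812.677125
Cer    34 1  C34H67NO3    537.512095
TG     52 2  C55H102O6    858.767641
TG     54 2  C57H106O6    886.798941
CE     18 2  C45H76O2     648.584532
FA     18 2  C18H32O2     280.240230
')
}

# --- Mann-Whitney enumeration oracle ------------------------------------
# Enumerates every assignment of the pooled observations to the two
# groups and computes the two-sided permutation p of the U statistic
# directly from the data (independent of the DP recursion in the
# implementation).
uTestEnumOracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  uStat <- function(a, b) sum(outer(a, b, ">")) + sum(outer(a, b, "==")) / 2
  obs <- uStat(x, y)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) uStat(pooled[idx], pooled[-idx]))
  mean(abs(us - n * m / 2) >= abs(obs - n * m / 2) - 1e-9)
}

# --- NIPALS PLS1 oracle -------------------------------------------------
# Textbook iterative NIPALS for the first PLS1 component on a scaled X
# and centered y; returns unit weight vector, scores and x-loadings.
nipalsPls1 <- function(Xs, yc, maxIter = 500, tol = 1e-12) {
  u <- yc
  w <- drop(crossprod(Xs, u)); w <- w / sqrt(sum(w^2))
  for (i in seq_len(maxIter)) {
    t <- drop(Xs %*% w)
    q <- sum(yc * t) / sum(t^2)
    u <- yc * q
    wNew <- drop(crossprod(Xs, u)); wNew <- wNew / sqrt(sum(wNew^2))
    if (sum((wNew - w)^2) < tol) { w <- wNew; break }
    w <- wNew
  }
  t <- drop(Xs %*% w)
  list(w = w, t = t, p = drop(crossprod(Xs, t)) / sum(t^2))
}

# --- hypergeometric enumeration oracle ----------------------------------
# Upper tail by direct summation of the combinatorial mass function.
hyperEnumOracle <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# --- shared fixtures ----------------------------------------------------
smallCohort <- function(seed = 11, nFeatures = 60,
                        groupSizes = c(control = 10L, UF = 12L, RUF = 10L),
                        markers = NULL) {
  if (is.null(markers))
    markers <- data.frame(name = character(), comparison = character(),
                          log2fc = numeric(), groups = character())
  cfg <- simulationConfig(groupSizes = groupSizes, nFeatures = nFeatures,
                          markers = markers, seed = seed)
  simulateCohort(cfg)
}
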