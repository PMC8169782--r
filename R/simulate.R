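# Synthetic cohort generator: three-group study design with log-normal
# intensities, planted fold changes on a marker subset, m/z values drawn
# from the theoretical database with ppm-scale noise, pooled QC
# injections, and matching MS1 / MS/MS spectra. The planted truth is the
# oracle for every downstream stage.

# evaluate expr under a fixed seed without disturbing the caller's RNG
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Construct a simulation design
#'
#' @param groupSizes named integer vector: control, UF, RUF sample counts
#' @param nFeatures number of lipid features
#' @param markers data.frame with columns \code{name}, \code{comparison}
#'   ("control_vs_UF" or "UF_vs_RUF"), \code{log2fc}, \code{groups}
#'   (comma-separated group labels carrying the effect)
#' @param muMean,muSd distribution of per-feature base log10 intensity
#' @param cv within-group biological coefficient of variation
#' @param qcCv analytical coefficient of variation of replicate QC
#'   injections (pooled sample; analytical noise only)
#' @param ppmSigma sd of the m/z noise in ppm
#' @param polarity,mzRange emulated acquisition mode and window
#' @param nQC pooled QC injections
#' @param seed mandatory integer seed
#' @return a validated \linkS4class{SimulationConfig}
#' @seealso [presetStudyDesign()], [simulateCohort()]
#' @export
simulationConfig <- function(groupSizes = c(control = 15L, UF = 35L, RUF = 31L),
                             nFeatures = 267L,
                             markers = data.frame(name = character(),
                                                  comparison = character(),
                                                  log2fc = numeric(),
                                                  groups = character()),
                             muMean = 5, muSd = 0.5, cv = 0.3, qcCv = 0.1,
                             ppmSigma = 2, polarity = "positive",
                             mzRange = c(400, 1000), nQC = 8L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  gs <- as.integer(groupSizes)
  names(gs) <- names(groupSizes)
  new("SimulationConfig", groupSizes = gs, nFeatures = as.integer(nFeatures),
      markers = markers, muMean = muMean, muSd = muSd, cv = cv, qcCv = qcCv,
      ppmSigma = ppmSigma, polarity = polarity, mzRange = as.numeric(mzRange),
      nQC = as.integer(nQC), seed = as.integer(seed))
}

# Marker lipid names for the default design. Chain-level names keep the
# enrichment stage's linoleic (18:2) predicate exercisable.
.PRESET_MARKERS_CTRL_UF <- c(
  "LPC 18:2", "PC 16:0_20:3", "PC 18:0_18:1", "PC 18:0_20:3",
  "SM d18:1/22:0", "SM d18:1/22:1", "SM d18:1/24:0", "TG 18:0_18:1_18:1")
.PRESET_MARKERS_UF_RUF <- c(
  "CE 18:2", "CE 20:4", "PC 16:0_22:6", "PC 18:0_18:2", "SM d12:0/14:1",
  "SM d18:1/22:0", "SM d18:1/22:1", "SM d18:1/24:0", "SM d18:1/24:1",
  "SM d18:2/16:0", "SM d18:2/24:1", "TG 14:1_18:1_18:2",
  "TG 16:0_16:1_18:2", "TG 16:0_18:1_18:2", "TG 16:1_18:0_18:1",
  "TG 16:1_18:0_18:3", "TG 18:1_18:2_18:3")

#' Default three-group plasma study design
#'
#' The documented default cohort: 15 control / 35 UF / 31 RUF samples,
#' 267 plasma lipid features acquired in positive mode over m/z
#' 400-1000, within-group CV 0.3, 2 ppm mass noise, and 25 planted
#' markers: 8 disease markers (perturbed in both UF and RUF, the
#' control-vs-UF panel) and 17 recurrence markers (perturbed in RUF
#' only, the UF-vs-RUF panel), with effect magnitudes |log2 FC| drawn
#' uniformly from [0.6, 1.5] with random sign.
#'
#' @param seed integer seed (drives both the drawn effect sizes and,
#'   through [simulateCohort()], the cohort itself)
#' @return a \linkS4class{SimulationConfig}
#' @export
presetStudyDesign <- function(seed = 1L) {
  n1 <- length(.PRESET_MARKERS_CTRL_UF)
  n2 <- length(.PRESET_MARKERS_UF_RUF)
  fc <- withSeed(as.integer(seed) + 104729L, {
    mag <- stats::runif(n1 + n2, 0.6, 1.5)
    sgn <- sample(c(-1, 1), n1 + n2, replace = TRUE)
    mag * sgn
  })
  markers <- data.frame(
    name = c(.PRESET_MARKERS_CTRL_UF, .PRESET_MARKERS_UF_RUF),
    comparison = rep(c("control_vs_UF", "UF_vs_RUF"), c(n1, n2)),
    log2fc = fc,
    groups = rep(c("UF,RUF", "RUF"), c(n1, n2)),
    stringsAsFactors = FALSE)
  simulationConfig(markers = markers, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
            collapse = "/"),
      "samples,", object@nFeatures, "features\n")
  cat("  markers:", nrow(object@markers), "| CV:", object@cv,
      "| ppm sigma:", object@ppmSigma, "| seed:", object@seed, "\n")
})

#' Simulate a cohort feature table with planted ground truth
#'
#' Per feature f and sample s in group g, intensity is
#' \code{10^(mu_f + log10(2) * FC(f, g) + N(0, sigma))} where
#' \code{mu_f ~ N(muMean, muSd)} is drawn once per feature and
#' \code{sigma} reproduces the configured raw-scale coefficient of
#' variation (\code{sigma_ln = sqrt(log(1 + cv^2))}). QC injections are
#' drawn
#' around the size-weighted pooled mean with the analytical
#' \code{qcCv} only (replicate injections of one pooled sample carry no
#' biological variance). Each feature carries the
#' identity and m/z (with ppm-scale noise) of a distinct theoretical ion;
#' planted markers carry the configured lipid names. Fully reproducible
#' from the config seed.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param db optional \linkS4class{LipidDatabase}; by default one is
#'   built for the configured polarity and m/z window
#' @return list with elements \code{features}
#'   (\linkS4class{LipidFeatureSet}) and \code{truth}
#'   (\linkS4class{GroundTruth})
#' @export
simulateCohort <- function(config, db = NULL) {
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) stop("invalid config: ", v)
  if (is.null(db))
    db <- buildLipidDatabase(polarity = config@polarity,
                             mzRange = config@mzRange)
  ions <- ionsOf(db)
  mk <- config@markers
  withSeed(config@seed, {
    nF <- config@nFeatures
    # resolve marker names to database ions (preferred = first class adduct)
    mkIon <- integer(nrow(mk))
    if (nrow(mk)) {
      parsed <- parseLipidName(mk$name)
      for (i in seq_len(nrow(mk))) {
        cand <- which(ions$class == parsed$class[i] &
                      ions$C == parsed$C[i] & ions$D == parsed$D[i])
        if (!length(cand))
          stop("marker ", mk$name[i], " has no ion in the database window")
        mkIon[i] <- cand[1]
      }
    }
    pool <- setdiff(seq_len(nrow(ions)), mkIon)
    if (length(pool) < nF - nrow(mk))
      stop("database too small for ", nF, " distinct features")
    others <- sample(pool, nF - nrow(mk))
    mkIdx <- if (nrow(mk)) sort(sample(nF, nrow(mk))) else integer()
    ionIdx <- integer(nF)
    ionIdx[mkIdx] <- mkIon
    ionIdx[setdiff(seq_len(nF), mkIdx)] <- others

    groups <- rep(names(config@groupSizes), config@groupSizes)
    nS <- length(groups)
    sigma10 <- sqrt(log(1 + config@cv^2)) / log(10)
    mu <- stats::rnorm(nF, config@muMean, config@muSd)

    # log2 fold-change matrix, features x groups
    fcg <- matrix(0, nF, 3, dimnames = list(NULL, names(config@groupSizes)))
    if (nrow(mk)) {
      for (i in seq_len(nrow(mk))) {
        gg <- strsplit(mk$groups[i], ",")[[1]]
        fcg[mkIdx[i], gg] <- fcg[mkIdx[i], gg] + mk$log2fc[i]
      }
    }
    logI <- outer(mu, rep(1, nS)) + log10(2) * fcg[, groups] +
      matrix(stats::rnorm(nF * nS, 0, sigma10), nF, nS)
    # pooled QC around the size-weighted mean of the group means
    w <- config@groupSizes / sum(config@groupSizes)
    sigmaQC <- sqrt(log(1 + config@qcCv^2)) / log(10)
    muQC <- mu + log10(2) * as.numeric(fcg %*% w)
    logQC <- outer(muQC, rep(1, config@nQC)) +
      matrix(stats::rnorm(nF * config@nQC, 0, sigmaQC), nF, config@nQC)
    x <- 10^cbind(logI, logQC)

    fid <- sprintf("F%04d", seq_len(nF))
    annotation <- ions$name[ionIdx]
    annotation[mkIdx] <- mk$name  # chain-level names for planted markers
    obsMz <- ions$mz[ionIdx] *
      (1 + stats::rnorm(nF, 0, config@ppmSigma) * 1e-6)

    sampleData <- data.frame(
      sample_id = c(paste0(groups, stats::ave(seq_len(nS), groups,
                                              FUN = seq_along)),
                    paste0("QC", seq_len(config@nQC))),
      group = c(groups, rep("QC", config@nQC)),
      matrix = "plasma",
      is_qc = c(rep(FALSE, nS), rep(TRUE, config@nQC)),
      stringsAsFactors = FALSE)
    fs <- LipidFeatureSet(x,
      featureData = data.frame(feature_id = fid, mz = obsMz,
                               annotation = annotation,
                               stringsAsFactors = FALSE),
      sampleData = sampleData)
    truth <- new("GroundTruth",
      markers = if (nrow(mk))
        data.frame(feature_id = fid[mkIdx], name = mk$name,
                   comparison = mk$comparison, log2fc = mk$log2fc,
                   groups = mk$groups, stringsAsFactors = FALSE)
      else data.frame(feature_id = character(), name = character(),
                      comparison = character(), log2fc = numeric(),
                      groups = character()),
      features = data.frame(feature_id = fid, name = ions$name[ionIdx],
                            class = ions$class[ionIdx], C = ions$C[ionIdx],
                            D = ions$D[ionIdx], adduct = ions$adduct[ionIdx],
                            theoretical_mz = ions$mz[ionIdx],
                            stringsAsFactors = FALSE),
      config = config)
    list(features = fs, truth = truth)
  })
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@features), "features,",
      nrow(object@markers), "planted markers\n")
  if (nrow(object@markers))
    print(table(object@markers$comparison))
})

#' Planted markers of a ground truth
#' @param truth a \linkS4class{GroundTruth}
#' @param comparison optional filter ("control_vs_UF" or "UF_vs_RUF")
#' @return data.frame of planted markers
#' @export
plantedMarkers <- function(truth, comparison = NULL) {
  m <- truth@markers
  if (!is.null(comparison)) m <- m[m$comparison == comparison, , drop = FALSE]
  m
}

#' True feature identities of a ground truth
#' @param truth a \linkS4class{GroundTruth}
#' @return data.frame of per-feature true lipid identities
#' @export
trueFeatures <- function(truth) truth@features

#' Simulate MS1 and MS/MS spectra for a simulated cohort
#'
#' Emits one MS1 peak per true feature ion at its theoretical m/z plus
#' Gaussian ppm noise (restricted to the configured acquisition window),
#' and one MS/MS spectrum per feature containing the class-diagnostic
#' fragments of its lipid class (classes without a rule get a bare
#' precursor spectrum).
#'
#' @param truth a \linkS4class{GroundTruth}
#' @param db the \linkS4class{LipidDatabase} the truth was drawn from
#' @param ppmSigma m/z noise sd in ppm (default: the config's value)
#' @param seed seed for the noise stream (default: config seed + 1)
#' @return list with \code{ms1} (a \linkS4class{Spectrum}) and
#'   \code{msms} (named list of MS/MS \linkS4class{Spectrum}, one per
#'   feature id)
#' @export
simulateSpectra <- function(truth, db, ppmSigma = NULL, seed = NULL) {
  cfg <- truth@config
  if (is.null(ppmSigma)) ppmSigma <- cfg@ppmSigma
  if (is.null(seed)) seed <- cfg@seed + 1L
  ft <- truth@features
  ions <- ionsOf(db)
  known <- paste(ions$name, ions$adduct)
  miss <- !(paste(ft$name, ft$adduct) %in% known)
  if (any(miss))
    stop("species not in database: ",
         paste(ft$name[miss], collapse = ", "))
  rules <- fragmentRules()
  nh3 <- monoisotopicMass(elementComposition(N = 1, H = 3))
  withSeed(as.integer(seed), {
    mzObs <- ft$theoretical_mz *
      (1 + stats::rnorm(nrow(ft), 0, ppmSigma) * 1e-6)
    inWin <- mzObs >= cfg@mzRange[1] & mzObs <= cfg@mzRange[2]
    ms1 <- Spectrum(mzObs[inWin], rep(1e5, sum(inWin)),
                    polarity = cfg@polarity, msLevel = 1L)
    msms <- vector("list", nrow(ft))
    names(msms) <- ft$feature_id
    for (i in seq_len(nrow(ft))) {
      prec <- mzObs[i]
      rr <- rules[rules$class == ft$class[i] &
                  rules$polarity == cfg@polarity, , drop = FALSE]
      frag <- numeric()
      for (j in seq_len(nrow(rr)))
        frag <- c(frag, switch(rr$type[j],
          fragment = rr$value[j],
          neutral_loss = prec - rr$value[j],
          acyl_loss = {
            fC <- max(12L, min(22L, 2L * round(ft$C[i] / 6)))
            prec - monoisotopicMass(
              lipidComposition("FA", fC, 0L, checkRange = FALSE)) - nh3
          }))
      msms[[i]] <- Spectrum(c(frag, prec),
                            c(rep(5e4, length(frag)), 1e4),
                            polarity = cfg@polarity, msLevel = 2L,
                            precursorMz = prec)
    }
    list(ms1 = ms1, msms = msms)
  })
}
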