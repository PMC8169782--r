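# End-to-end orchestration: preprocessing, pairwise Mann-Whitney
# screening, OPLS-DA on the significant set, VIP > 1 panel selection,
# logistic diagnostic model with LOOCV performance, and lipid-set
# enrichment, with a machine-readable report.

#' Pipeline configuration
#'
#' Either \code{simConfig} (a \linkS4class{SimulationConfig}; the cohort
#' is generated) or \code{tablePath} + \code{samplesPath} (a cohort is
#' read from disk) must be given.
#'
#' @param simConfig a \linkS4class{SimulationConfig}, or NULL
#' @param tablePath,samplesPath feature-table CSV paths, or NULL
#' @param comparisons list of length-2 character vectors; within each,
#'   the second group is the class coded 1
#' @param alpha Mann-Whitney significance level
#' @param nOrtho,folds OPLS-DA settings
#' @param vipThreshold VIP cutoff for panel selection
#' @param logisticThreshold LOOCV classification threshold
#' @param maxRsd QC RSD filter threshold
#' @param seed mandatory integer seed for every random stage
#' @return validated configuration list
#' @export
pipelineConfig <- function(simConfig = NULL, tablePath = NULL,
                           samplesPath = NULL,
                           comparisons = list(c("control", "UF"),
                                              c("control", "RUF"),
                                              c("UF", "RUF")),
                           alpha = 0.05, nOrtho = 1L, folds = 7L,
                           vipThreshold = 1.0, logisticThreshold = 0.5,
                           maxRsd = 0.30, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(simConfig) && (is.null(tablePath) || is.null(samplesPath)))
    stop("give either simConfig or tablePath + samplesPath")
  stopifnot(all(vapply(comparisons, length, 1L) == 2L))
  structure(list(simConfig = simConfig, tablePath = tablePath,
                 samplesPath = samplesPath, comparisons = comparisons,
                 alpha = alpha, nOrtho = as.integer(nOrtho),
                 folds = as.integer(folds), vipThreshold = vipThreshold,
                 logisticThreshold = logisticThreshold, maxRsd = maxRsd,
                 seed = as.integer(seed)),
            class = "lipidPipelineConfig")
}

#' Run the full biomarker-discovery pipeline
#'
#' Stage order per comparison: two-sided Mann-Whitney screening on the
#' normalized intensities (raw p < alpha), OPLS-DA on the log10
#' intensities of exactly the significant features, VIP > threshold
#' panel selection, logistic diagnostic model on the raw-scale panel
#' intensities with LOOCV sensitivity/specificity, and hypergeometric
#' enrichment of the significant lipid names against all analyzed
#' lipids. Deterministic for a fixed seed.
#'
#' @param config from [pipelineConfig()]
#' @param outDir optional directory; when given, report.json and
#'   per-stage TSVs are written there
#' @param quiet suppress stage messages
#' @return the pipeline report (nested list, class
#'   \code{lipidPipelineReport})
#' @export
runPipeline <- function(config, outDir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "lipidPipelineConfig"))
  say <- function(...) if (!quiet) message(...)
  truth <- NULL
  if (!is.null(config$simConfig)) {
    say("stage simulate: generating synthetic cohort")
    sim <- simulateCohort(config$simConfig)
    fs <- sim$features; truth <- sim$truth
  } else {
    say("stage read: ", config$tablePath)
    fs <- readFeatureTable(config$tablePath, config$samplesPath)
  }
  nIn <- nrow(fs)
  fs <- withCallingHandlers(
    preprocess(fs, maxRsd = config$maxRsd),
    warning = function(w) { say("  preprocess: ", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  say(sprintf("stage preprocess: %d -> %d features", nIn, nrow(fs)))
  background <- featureAnnotations(fs)
  background <- background[!is.na(background)]
  xAll <- intensityMatrix(fs)
  groups <- sampleGroups(fs)
  qc <- isQC(fs)

  comps <- list()
  for (ci in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[ci]]
    key <- paste(cmp, collapse = "_vs_")
    seedC <- config$seed + ci
    diff <- differentialLipids(fs, cmp[1], cmp[2], alpha = config$alpha)
    sig <- diff$feature_id[diff$significant]
    say(sprintf("stage stats [%s]: %d / %d significant at p < %g",
                key, length(sig), nrow(diff), config$alpha))
    block <- list(groups = cmp, nFeatures = nrow(diff),
                  nSignificant = length(sig), differential = diff)
    if (length(sig) >= 3) {
      keep <- groups %in% cmp & !qc
      y <- factor(groups[keep], levels = cmp)
      Xlog <- t(log10(xAll[sig, keep, drop = FALSE]))
      opls <- fitOpls(Xlog, y, nOrtho = config$nOrtho,
                      folds = config$folds, seed = seedC)
      panel <- selectMarkers(opls, config$vipThreshold)
      say(sprintf("stage opls [%s]: R2X=%.3f R2Y=%.3f Q2Y=%.3f; VIP>%g: %d",
                  key, opls@R2X, opls@R2Y, opls@Q2Y, config$vipThreshold,
                  length(panel)))
      block$opls <- list(R2X = opls@R2X, R2Y = opls@R2Y, Q2Y = opls@Q2Y,
                         nOrtho = opls@nOrtho, folds = opls@folds)
      block$vip <- data.frame(feature_id = names(vipScores(opls)),
                              vip = unname(vipScores(opls)),
                              stringsAsFactors = FALSE)
      block$panel <- panel
      if (length(panel) >= 1) {
        Xraw <- t(xAll[panel, keep, drop = FALSE])
        lm <- suppressWarnings(fitLogisticPanel(Xraw, y))
        perf <- suppressWarnings(
          loocvPerformance(Xraw, y, threshold = config$logisticThreshold))
        say(sprintf(
          "stage diagnose [%s]: LOOCV sensitivity=%.3f specificity=%.3f",
          key, perf@sensitivity, perf@specificity))
        block$logistic <- coefficientTable(lm)
        block$logisticMeta <- list(converged = lm@converged,
                                   separation = lm@separation)
        block$performance <- list(
          sensitivity = perf@sensitivity, specificity = perf@specificity,
          tp = perf@tp, fp = perf@fp, tn = perf@tn, fn = perf@fn,
          threshold = perf@threshold, excluded = perf@excluded)
      }
    } else {
      say(sprintf("stage opls [%s]: skipped (%d significant features < 3)",
                  key, length(sig)))
    }
    sigAnn <- diff$annotation[diff$significant & !is.na(diff$annotation)]
    block$enrichment <- enrichLipidSets(sigAnn, background)
    comps[[key]] <- block
  }
  report <- structure(list(
    provenance = list(
      package = "lipidScreen",
      version = as.character(utils::packageVersion("lipidScreen")),
      seed = config$seed, alpha = config$alpha, nOrtho = config$nOrtho,
      folds = config$folds, vipThreshold = config$vipThreshold,
      logisticThreshold = config$logisticThreshold,
      simulated = !is.null(config$simConfig)),
    nFeaturesInput = nIn, nFeaturesAnalyzed = nrow(fs),
    comparisons = comps), class = "lipidPipelineReport")
  attr(report, "featureSet") <- fs
  attr(report, "truth") <- truth
  if (!is.null(outDir)) writePipelineReport(report, outDir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes \code{report.json} (the full report) plus per-comparison TSVs
#' of the differential test, VIP table, logistic coefficients and
#' enrichment. Output is byte-identical across runs with the same seed.
#'
#' @param report a \code{lipidPipelineReport}
#' @param outDir output directory (created if absent)
#' @return \code{outDir}, invisibly
#' @export
writePipelineReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (key in names(report$comparisons)) {
    blk <- report$comparisons[[key]]
    wt <- function(df, stem)
      utils::write.table(df, file.path(outDir, paste0(key, "_", stem,
                                                      ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    wt(blk$differential, "differential")
    if (!is.null(blk$vip)) wt(blk$vip, "vip")
    if (!is.null(blk$logistic)) wt(blk$logistic, "logistic")
    wt(blk$enrichment, "enrichment")
  }
  invisible(outDir)
}

#' @export
print.lipidPipelineReport <- function(x, ...) {
  cat("lipidScreen pipeline report (seed", x$provenance$seed, ")\n")
  cat(sprintf("  features: %d input, %d analyzed\n",
              x$nFeaturesInput, x$nFeaturesAnalyzed))
  for (key in names(x$comparisons)) {
    b <- x$comparisons[[key]]
    cat(sprintf("  %s: %d significant", key, b$nSignificant))
    if (!is.null(b$opls))
      cat(sprintf("; R2Y=%.2f Q2Y=%.2f; panel=%d",
                  b$opls$R2Y, b$opls$Q2Y, length(b$panel)))
    if (!is.null(b$performance))
      cat(sprintf("; LOOCV se=%.2f sp=%.2f",
                  b$performance$sensitivity, b$performance$specificity))
    cat("\n")
  }
  invisible(x)
}
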