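#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Theoretical lipid ion database
#'
#' Container for an enumerated set of theoretical lipid ions: every
#' (species, adduct) combination allowed by the configured lipid classes,
#' total acyl-carbon and double-bond ranges, held sorted by m/z for fast
#' window queries.
#'
#' @slot ions data.frame with columns \code{name}, \code{class}, \code{C},
#'   \code{D}, \code{formula}, \code{mass}, \code{adduct}, \code{polarity},
#'   \code{mz}, sorted ascending by \code{mz}.
#' @slot params list recording the build parameters (classes, ranges,
#'   adducts, m/z window).
#'
#' @seealso [buildLipidDatabase()], [queryMz()]
#' @export
setClass("LipidDatabase",
  representation(ions = "data.frame", params = "list"))

setValidity("LipidDatabase", function(object) {
  ions <- object@ions
  need <- c("name", "class", "C", "D", "formula", "mass", "adduct",
            "polarity", "mz")
  if (!all(need %in% names(ions)))
    return(paste("ions must have columns:", paste(need, collapse = ", ")))
  if (nrow(ions)) {
    if (is.unsorted(ions$mz)) return("ions must be sorted ascending by m/z")
    if (anyDuplicated(paste(ions$name, ions$adduct)))
      return("duplicate (species, adduct) pairs")
    if (any(ions$mz <= 0)) return("non-positive m/z")
  }
  TRUE
})

#' Mass spectrum
#'
#' A single MS1 or MS/MS spectrum: a peak list (m/z, intensity) with
#' polarity, MS level and, for MS/MS, the precursor m/z.
#'
#' @slot peaks data.frame with columns \code{mz}, \code{intensity},
#'   sorted ascending by m/z.
#' @slot polarity "positive" or "negative".
#' @slot msLevel 1 or 2.
#' @slot precursorMz precursor m/z (MS/MS only; \code{NA_real_} for MS1).
#'
#' @export
setClass("Spectrum",
  representation(peaks = "data.frame", polarity = "character",
                 msLevel = "integer", precursorMz = "numeric"))

setValidity("Spectrum", function(object) {
  p <- object@peaks
  if (!all(c("mz", "intensity") %in% names(p)))
    return("peaks must have columns mz, intensity")
  if (nrow(p)) {
    if (any(p$mz <= 0)) return("non-positive m/z")
    if (any(p$intensity < 0)) return("negative intensity")
    if (is.unsorted(p$mz)) return("peaks must be sorted by m/z")
  }
  if (!object@polarity %in% c("positive", "negative"))
    return("polarity must be 'positive' or 'negative'")
  if (!object@msLevel %in% c(1L, 2L)) return("msLevel must be 1 or 2")
  if (object@msLevel == 2L && is.na(object@precursorMz))
    return("MS/MS spectrum requires a precursor m/z")
  TRUE
})

#' Lipid feature-by-sample container
#'
#' Extends \linkS4class{SummarizedExperiment}: one \code{intensity} assay
#' (features x samples, non-negative), feature metadata (\code{feature_id},
#' \code{mz}, \code{annotation}) in \code{rowData} and sample metadata
#' (\code{group}, \code{matrix}, \code{is_qc}) in \code{colData}.
#'
#' @seealso [LipidFeatureSet()], [readFeatureTable()]
#' @export
setClass("LipidFeatureSet", contains = "SummarizedExperiment")

.VALID_GROUPS  <- c("control", "UF", "RUF", "QC")
.VALID_MATRIX  <- c("plasma", "myometrium", "fibroid")

setValidity("LipidFeatureSet", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  x <- SummarizedExperiment::assay(object, "intensity")
  if (any(x < 0, na.rm = TRUE)) return("negative intensities")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("feature_id", "mz", "annotation") %in% names(rd)))
    return("rowData must have feature_id, mz, annotation")
  if (anyDuplicated(rd$feature_id)) return("duplicate feature ids")
  if (!all(c("group", "matrix", "is_qc") %in% names(cd)))
    return("colData must have group, matrix, is_qc")
  if (!all(cd$group %in% .VALID_GROUPS))
    return(paste("group labels must be in:", paste(.VALID_GROUPS, collapse = ", ")))
  if (!all(cd$matrix %in% .VALID_MATRIX))
    return(paste("matrix labels must be in:", paste(.VALID_MATRIX, collapse = ", ")))
  if (!is.logical(cd$is_qc)) return("is_qc must be logical")
  TRUE
})

#' Synthetic cohort design
#'
#' Parameters of the synthetic three-group cohort generator: group sizes,
#' feature count, planted marker effects, log-normal intensity parameters,
#' m/z noise and acquisition window, and the mandatory seed.
#'
#' @slot groupSizes named integer vector (control, UF, RUF), each >= 2.
#' @slot nFeatures number of lipid features.
#' @slot markers data.frame with columns \code{name} (lipid name),
#'   \code{comparison} ("control_vs_UF" or "UF_vs_RUF"), \code{log2fc},
#'   and \code{groups} (comma-separated affected groups).
#' @slot muMean,muSd mean and sd of the per-feature base log10 intensity.
#' @slot cv within-group biological coefficient of variation of raw
#'   intensities.
#' @slot qcCv analytical coefficient of variation of replicate QC
#'   injections of the pooled sample.
#' @slot ppmSigma sd of the multiplicative m/z noise, in ppm.
#' @slot polarity ion mode of the emulated acquisition.
#' @slot mzRange acquisition m/z window, length 2.
#' @slot nQC number of pooled quality-control injections.
#' @slot seed integer seed driving all randomness.
#'
#' @seealso [simulationConfig()], [presetStudyDesign()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(groupSizes = "integer", nFeatures = "integer",
                 markers = "data.frame", muMean = "numeric", muSd = "numeric",
                 cv = "numeric", qcCv = "numeric", ppmSigma = "numeric",
                 polarity = "character",
                 mzRange = "numeric", nQC = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  bad <- character()
  if (length(object@groupSizes) != 3L ||
      !identical(names(object@groupSizes), c("control", "UF", "RUF")))
    bad <- c(bad, "groupSizes must be named (control, UF, RUF)")
  if (any(object@groupSizes < 2L)) bad <- c(bad, "group sizes must be >= 2")
  if (object@nFeatures < 1L) bad <- c(bad, "nFeatures must be >= 1")
  m <- object@markers
  if (nrow(m)) {
    if (!all(c("name", "comparison", "log2fc", "groups") %in% names(m)))
      bad <- c(bad, "markers needs columns name, comparison, log2fc, groups")
    else if (nrow(m) > object@nFeatures)
      bad <- c(bad, "more markers than features")
  }
  if (object@cv <= 0) bad <- c(bad, "cv must be > 0")
  if (object@qcCv <= 0) bad <- c(bad, "qcCv must be > 0")
  if (object@ppmSigma < 0) bad <- c(bad, "ppmSigma must be >= 0")
  if (length(object@mzRange) != 2L || object@mzRange[1] >= object@mzRange[2])
    bad <- c(bad, "mzRange must be an increasing length-2 window")
  if (length(object@seed) != 1L || is.na(object@seed))
    bad <- c(bad, "seed is mandatory")
  if (length(bad)) paste(bad, collapse = "; ") else TRUE
})

#' Planted ground truth of a simulated cohort
#'
#' @slot markers data.frame of planted markers: \code{feature_id},
#'   \code{name}, \code{comparison}, \code{log2fc}, \code{groups}.
#' @slot features data.frame of true identities per feature:
#'   \code{feature_id}, \code{name}, \code{class}, \code{C}, \code{D},
#'   \code{adduct}, \code{theoretical_mz}.
#' @slot config the \linkS4class{SimulationConfig} that produced it.
#'
#' @export
setClass("GroundTruth",
  representation(markers = "data.frame", features = "data.frame",
                 config = "SimulationConfig"))

#' Fitted OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis:
#' one predictive component plus \code{nOrtho} y-orthogonal components,
#' with explained-variance summaries, cross-validated Q2Y and per-feature
#' VIP scores.
#'
#' @slot weights,loadings,scores predictive component w (unit norm),
#'   p, and t.
#' @slot yLoading scalar q.
#' @slot orthoWeights,orthoLoadings,orthoScores matrices (one column per
#'   orthogonal component; zero columns when \code{nOrtho = 0}).
#' @slot R2X,R2Y,Q2Y modeled X-variance, explained and cross-validated
#'   predicted y-variance fractions.
#' @slot vip named per-feature variable importance in projection;
#'   \code{sum(vip^2) == nFeatures}.
#' @slot scaling list: \code{center}, \code{scale}, \code{mode},
#'   \code{keep} (features retained after zero-variance filtering).
#' @slot yLevels class labels in coding order (second level coded 1).
#' @slot yMean mean of the 0/1-coded response.
#' @slot nOrtho,folds,seed model configuration.
#'
#' @seealso [fitOpls()], [vipScores()], [selectMarkers()]
#' @export
setClass("OplsModel",
  representation(weights = "numeric", loadings = "numeric", scores = "numeric",
                 yLoading = "numeric", orthoWeights = "matrix",
                 orthoLoadings = "matrix", orthoScores = "matrix",
                 R2X = "numeric", R2Y = "numeric", Q2Y = "numeric",
                 vip = "numeric", scaling = "list", yLevels = "character",
                 yMean = "numeric", nOrtho = "integer", folds = "integer",
                 seed = "integer"))

#' Logistic diagnostic model over a marker panel
#'
#' Maximum-likelihood logistic regression (IRLS with a tiny ridge for
#' numerical stability) of disease class on raw marker intensities,
#' y = 1 / (1 + exp(-(b0 + b . I))).
#'
#' @slot coefficients named vector, first element \code{(Intercept)}.
#' @slot se,z,p per-coefficient Wald statistics.
#' @slot ci 95 percent confidence intervals (matrix, columns lower/upper).
#' @slot converged,iterations,separation fit diagnostics.
#' @slot ridgeLambda ridge penalty applied to standardized slopes.
#' @slot yLevels class labels in coding order (second level coded 1).
#'
#' @seealso [fitLogisticPanel()], [predictProb()]
#' @export
setClass("LogisticModel",
  representation(coefficients = "numeric", se = "numeric", z = "numeric",
                 p = "numeric", ci = "matrix", converged = "logical",
                 iterations = "integer", separation = "logical",
                 ridgeLambda = "numeric", yLevels = "character"))

#' Cross-validated diagnostic performance
#'
#' Leave-one-out confusion counts and the derived sensitivity and
#' specificity of a diagnostic model at a fixed probability threshold.
#'
#' @slot tp,fp,tn,fn confusion counts.
#' @slot sensitivity TP / (TP + FN).
#' @slot specificity TN / (TN + FP).
#' @slot threshold classification threshold on the predicted probability.
#' @slot excluded samples skipped because their training fold lost a class.
#'
#' @seealso [loocvPerformance()]
#' @export
setClass("DiagnosticPerformance",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", sensitivity = "numeric",
                 specificity = "numeric", threshold = "numeric",
                 excluded = "integer"))

setValidity("DiagnosticPerformance", function(object) {
  ok <- function(a, b) isTRUE(all.equal(a, b)) || (is.nan(a) && is.nan(b))
  den1 <- object@tp + object@fn
  den0 <- object@tn + object@fp
  if (den1 > 0 && !ok(object@sensitivity, object@tp / den1))
    return("sensitivity inconsistent with confusion counts")
  if (den0 > 0 && !ok(object@specificity, object@tn / den0))
    return("specificity inconsistent with confusion counts")
  TRUE
})
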