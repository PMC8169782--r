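#' Query a database within a mass-accuracy window
#'
#' @param db a \linkS4class{LipidDatabase}
#' @param mz query m/z
#' @param tolPpm tolerance in ppm
#' @name queryMz
#' @export
setGeneric("queryMz", function(db, mz, tolPpm = 10) standardGeneric("queryMz"))

#' Variable importance in projection
#'
#' @param model a fitted \linkS4class{OplsModel}
#' @name vipScores
#' @export
setGeneric("vipScores", function(model) standardGeneric("vipScores"))

#' Select marker features by VIP
#'
#' @param model a fitted \linkS4class{OplsModel}
#' @param threshold VIP cutoff (strict inequality)
#' @name selectMarkers
#' @export
setGeneric("selectMarkers", function(model, threshold = 1.0)
  standardGeneric("selectMarkers"))

#' Predicted class-1 probability of a diagnostic model
#'
#' @param model a fitted \linkS4class{LogisticModel}
#' @param newdata marker intensity vector or matrix
#' @name predictProb
#' @export
setGeneric("predictProb", function(model, newdata) standardGeneric("predictProb"))

#' Intensity matrix accessor
#'
#' @param object a \linkS4class{LipidFeatureSet}
#' @return numeric matrix, features x samples
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' Sample group labels
#'
#' @param object a \linkS4class{LipidFeatureSet}
#' @return character vector of group labels, one per sample
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' QC sample flag
#'
#' @param object a \linkS4class{LipidFeatureSet}
#' @return logical vector, TRUE for pooled quality-control injections
#' @export
setGeneric("isQC", function(object) standardGeneric("isQC"))

#' Feature m/z values
#'
#' @param object a \linkS4class{LipidFeatureSet}
#' @return numeric vector of feature m/z values
#' @export
setGeneric("featureMz", function(object) standardGeneric("featureMz"))

#' Feature annotations
#'
#' @param object a \linkS4class{LipidFeatureSet}
#' @return character vector of lipid names (NA where unannotated)
#' @export
setGeneric("featureAnnotations", function(object)
  standardGeneric("featureAnnotations"))
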