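# Feature table container, delimited-text I/O and preprocessing
# (half-minimum imputation, QC-based RSD filtering, TIC normalization).

#' Construct a LipidFeatureSet
#'
#' @param intensity numeric matrix, features x samples, non-negative
#' @param featureData data.frame with feature_id, mz, annotation (one row
#'   per feature); defaults are generated when NULL
#' @param sampleData data.frame with sample_id, group, matrix, is_qc (one
#'   row per sample)
#' @return a \linkS4class{LipidFeatureSet}
#' @export
LipidFeatureSet <- function(intensity, featureData = NULL, sampleData = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(featureData))
    featureData <- data.frame(
      feature_id = sprintf("F%04d", seq_len(nrow(intensity))),
      mz = NA_real_, annotation = NA_character_)
  if (is.null(sampleData))
    sampleData <- data.frame(
      sample_id = sprintf("S%03d", seq_len(ncol(intensity))),
      group = "control", matrix = "plasma", is_qc = FALSE)
  if (nrow(featureData) != nrow(intensity))
    stop("featureData rows (", nrow(featureData),
         ") do not match intensity rows (", nrow(intensity), ")")
  if (nrow(sampleData) != ncol(intensity))
    stop("sampleData rows (", nrow(sampleData),
         ") do not match intensity columns (", ncol(intensity), ")")
  rownames(intensity) <- featureData$feature_id
  colnames(intensity) <- sampleData$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(featureData[c("feature_id", "mz",
                                                 "annotation")]),
    colData = S4Vectors::DataFrame(sampleData[c("sample_id", "group",
                                                "matrix", "is_qc")],
                                   row.names = sampleData$sample_id))
  new("LipidFeatureSet", se)
}

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "LipidFeatureSet", function(object)
  SummarizedExperiment::assay(object, "intensity"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "LipidFeatureSet", function(object)
  as.character(SummarizedExperiment::colData(object)$group))

#' @rdname isQC
#' @export
setMethod("isQC", "LipidFeatureSet", function(object)
  SummarizedExperiment::colData(object)$is_qc)

#' @rdname featureMz
#' @export
setMethod("featureMz", "LipidFeatureSet", function(object)
  as.numeric(SummarizedExperiment::rowData(object)$mz))

#' @rdname featureAnnotations
#' @export
setMethod("featureAnnotations", "LipidFeatureSet", function(object)
  as.character(SummarizedExperiment::rowData(object)$annotation))

setMethod("show", "LipidFeatureSet", function(object) {
  g <- table(sampleGroups(object)[!isQC(object)])
  cat("LipidFeatureSet:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(g), g), collapse = ", "),
      "| QC:", sum(isQC(object)), "\n")
  ann <- featureAnnotations(object)
  cat("  annotated features:", sum(!is.na(ann)), "\n")
})

#' Read / write a feature table as delimited text
#'
#' The on-disk dialect is two CSV files: the table (rows = features;
#' columns \code{feature_id,mz,annotation} then one column per sample)
#' and the sample sheet (\code{sample_id,group,matrix,is_qc}). Values
#' round-trip losslessly.
#'
#' @param tablePath path to the intensity CSV
#' @param samplesPath path to the sample-metadata CSV
#' @return a \linkS4class{LipidFeatureSet}
#' @export
readFeatureTable <- function(tablePath, samplesPath) {
  tab <- utils::read.csv(tablePath, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta <- c("feature_id", "mz", "annotation")
  if (!all(meta %in% names(tab)))
    stop("table must start with columns: ", paste(meta, collapse = ", "))
  smp <- utils::read.csv(samplesPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "matrix", "is_qc") %in% names(smp)))
    stop("sample sheet needs columns sample_id, group, matrix, is_qc")
  dup <- tab$feature_id[duplicated(tab$feature_id)]
  if (length(dup))
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  sampleCols <- setdiff(names(tab), meta)
  if (!setequal(sampleCols, smp$sample_id))
    stop("sample columns do not match the sample sheet (",
         paste(setdiff(sampleCols, smp$sample_id), collapse = ", "), ")")
  x <- as.matrix(tab[, smp$sample_id, drop = FALSE])
  if (anyNA(suppressWarnings(storage.mode(x) <- "double")) || anyNA(x))
    stop("non-numeric or missing intensity values in ", tablePath)
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative intensity at feature ", tab$feature_id[neg[1, 1]],
         ", sample ", colnames(x)[neg[1, 2]])
  smp$is_qc <- as.logical(smp$is_qc)
  LipidFeatureSet(x, featureData = tab[meta], sampleData = smp)
}

#' @rdname readFeatureTable
#' @param fs a \linkS4class{LipidFeatureSet}
#' @export
writeFeatureTable <- function(fs, tablePath, samplesPath) {
  rd <- as.data.frame(SummarizedExperiment::rowData(fs))
  tab <- cbind(rd[c("feature_id", "mz", "annotation")],
               as.data.frame(intensityMatrix(fs), check.names = FALSE))
  utils::write.csv(tab, tablePath, row.names = FALSE, quote = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(fs))
  utils::write.csv(cd[c("sample_id", "group", "matrix", "is_qc")],
                   samplesPath, row.names = FALSE, quote = FALSE)
  invisible(tablePath)
}

#' Half-minimum imputation
#'
#' Replaces zeros and missing values of each feature by half that
#' feature's minimum positive intensity; features with no positive
#' values are dropped.
#'
#' @param fs a \linkS4class{LipidFeatureSet}
#' @return imputed \linkS4class{LipidFeatureSet}
#' @export
imputeHalfMin <- function(fs) {
  x <- intensityMatrix(fs)
  hasPos <- apply(x, 1, function(r) any(r > 0, na.rm = TRUE))
  x <- x[hasPos, , drop = FALSE]
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    miss <- is.na(r) | r == 0
    if (any(miss)) x[i, miss] <- min(r[r > 0], na.rm = TRUE) / 2
  }
  out <- fs[hasPos, ]
  SummarizedExperiment::assay(out, "intensity") <- x
  out
}

#' QC-based relative standard deviation filter
#'
#' Drops features whose relative standard deviation (sd / mean) across
#' the pooled QC injections exceeds \code{maxRsd}. Requires at least 3
#' QC samples; with fewer, the table is returned unchanged with a
#' warning. Non-QC intensities are never modified.
#'
#' @param fs a \linkS4class{LipidFeatureSet}
#' @param maxRsd maximum tolerated QC RSD (default 0.30)
#' @return filtered \linkS4class{LipidFeatureSet}
#' @export
qcRsdFilter <- function(fs, maxRsd = 0.30) {
  qc <- isQC(fs)
  if (sum(qc) < 3) {
    warning("fewer than 3 QC samples; RSD filter skipped")
    return(fs)
  }
  xq <- intensityMatrix(fs)[, qc, drop = FALSE]
  rsd <- apply(xq, 1, function(r) {
    m <- mean(r)
    if (m == 0) Inf else stats::sd(r) / m
  })
  fs[rsd <= maxRsd, ]
}

#' Total-ion-current normalization
#'
#' Scales every sample so its total intensity equals the median of the
#' original sample totals; within-sample feature ratios are preserved.
#'
#' @param fs a \linkS4class{LipidFeatureSet}
#' @return normalized \linkS4class{LipidFeatureSet}
#' @export
ticNormalize <- function(fs) {
  x <- intensityMatrix(fs)
  tot <- colSums(x)
  if (any(tot <= 0))
    stop("sample(s) with non-positive total intensity: ",
         paste(colnames(x)[tot <= 0], collapse = ", "))
  target <- stats::median(tot)
  x <- sweep(x, 2, target / tot, `*`)
  SummarizedExperiment::assay(fs, "intensity") <- x
  fs
}

#' Standard preprocessing chain
#'
#' Applies the fixed pipeline order: half-minimum imputation, QC RSD
#' filtering, TIC normalization.
#'
#' @param fs a \linkS4class{LipidFeatureSet}
#' @param maxRsd QC RSD threshold passed to [qcRsdFilter()]
#' @return preprocessed \linkS4class{LipidFeatureSet}
#' @export
preprocess <- function(fs, maxRsd = 0.30) {
  ticNormalize(qcRsdFilter(imputeHalfMin(fs), maxRsd = maxRsd))
}
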