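# Peak annotation: exact-mass matching of MS1 peaks against the
# theoretical database, MS/MS confirmation of class-diagnostic
# fragments, and deterministic ambiguity resolution.

#' Construct a mass spectrum
#'
#' @param mz,intensity peak list vectors (equal length)
#' @param polarity "positive" or "negative"
#' @param msLevel 1 (survey) or 2 (MS/MS)
#' @param precursorMz precursor m/z, required when \code{msLevel = 2}
#' @return a \linkS4class{Spectrum}
#' @export
Spectrum <- function(mz = numeric(), intensity = rep(1, length(mz)),
                     polarity = "positive", msLevel = 1L,
                     precursorMz = NA_real_) {
  o <- order(mz)
  intensity <- rep_len(as.numeric(intensity), length(mz))
  new("Spectrum",
      peaks = data.frame(mz = as.numeric(mz)[o],
                         intensity = intensity[o]),
      polarity = polarity, msLevel = as.integer(msLevel),
      precursorMz = as.numeric(precursorMz))
}

#' Peak list of a spectrum
#' @param x a \linkS4class{Spectrum}
#' @return data.frame with columns mz, intensity
#' @export
peaksOf <- function(x) x@peaks

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: MS%d, %s mode, %d peaks",
              object@msLevel, object@polarity, nrow(object@peaks)))
  if (object@msLevel == 2L)
    cat(sprintf(", precursor m/z %.4f", object@precursorMz))
  cat("\n")
})

#' Class-diagnostic MS/MS fragment rules
#'
#' Built-in confirmation rules: a candidate annotation is MS/MS-confirmed
#' when every mandatory entry for its class is found. Rule types:
#' \code{fragment} (an ion at a fixed m/z), \code{neutral_loss} (a peak at
#' precursor minus a fixed delta) and \code{acyl_loss} (TG under
#' ammoniated adducts: at least one peak matching the loss of a fatty
#' acid plus ammonia).
#'
#' @return data.frame with columns class, polarity, type, value, label
#' @export
fragmentRules <- function() {
  data.frame(
    class    = c("PC", "LPC", "SM", "PC-O", "PE", "PE-O", "PS", "CE",
                 "Cer", "TG"),
    polarity = c(rep("positive", 4), "positive", "positive", "negative",
                 "positive", "positive", "positive"),
    type     = c(rep("fragment", 4), "neutral_loss", "neutral_loss",
                 "neutral_loss", "fragment", "neutral_loss", "acyl_loss"),
    value    = c(184.0733, 184.0733, 184.0733, 184.0733,
                 141.0191, 141.0191, 87.0320, 369.3516, 18.0106, NA_real_),
    label    = c(rep("phosphocholine head 184.0733", 4),
                 "phosphoethanolamine loss 141.0191",
                 "phosphoethanolamine loss 141.0191",
                 "serine loss 87.0320", "cholestadienyl 369.3516",
                 "water loss", "acyl + NH3 loss"),
    stringsAsFactors = FALSE)
}

.hasPeakNear <- function(spec, mz, tol) {
  any(abs(spec@peaks$mz - mz) <= tol)
}

# candidate fatty-acid neutral masses for the TG acyl-loss rule
.faMasses <- function() {
  grid <- expand.grid(C = seq(12L, 22L, 2L), D = 0:6)
  grid <- grid[grid$D <= grid$C %/% 2, ]
  vapply(seq_len(nrow(grid)), function(i)
    monoisotopicMass(lipidComposition("FA", grid$C[i], grid$D[i],
                                      checkRange = FALSE)), numeric(1))
}

#' Annotate MS1 peaks by exact mass
#'
#' Matches every peak of a survey spectrum against the theoretical
#' database inside a ppm window; each (peak, candidate) pair inside the
#' window becomes one annotation row, candidates ranked by |ppm|.
#'
#' @param spectrum an MS1 \linkS4class{Spectrum}
#' @param db a \linkS4class{LipidDatabase} of matching polarity
#' @param tolPpm match tolerance in ppm (default 10)
#' @return data.frame with columns peak_mz, intensity, name, class, C, D,
#'   adduct, theoretical_mz, ppm, confirmed (NA until MS/MS confirmation)
#' @export
annotatePeaks <- function(spectrum, db, tolPpm = 10) {
  stopifnot(is(spectrum, "Spectrum"), is(db, "LipidDatabase"))
  if (spectrum@msLevel != 1L) stop("annotatePeaks expects an MS1 spectrum")
  pol <- unique(db@ions$polarity)
  if (length(pol) && !identical(pol, spectrum@polarity))
    stop("polarity mismatch: spectrum is ", spectrum@polarity,
         ", database is ", paste(pol, collapse = "/"))
  pk <- spectrum@peaks
  out <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    hit <- queryMz(db, pk$mz[i], tolPpm)
    if (!nrow(hit)) next
    out[[i]] <- data.frame(peak_mz = pk$mz[i], intensity = pk$intensity[i],
                           name = hit$name, class = hit$class,
                           C = hit$C, D = hit$D, adduct = hit$adduct,
                           theoretical_mz = hit$mz, ppm = hit$ppm,
                           confirmed = NA, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(peak_mz = numeric(), intensity = numeric(),
                      name = character(), class = character(),
                      C = integer(), D = integer(), adduct = character(),
                      theoretical_mz = numeric(), ppm = numeric(),
                      confirmed = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Confirm annotations with an MS/MS spectrum
#'
#' Sets \code{confirmed = TRUE} for candidate annotations of one peak
#' when every mandatory class-diagnostic fragment is present in the
#' MS/MS spectrum within \code{fragTolDa}. Classes without a rule stay
#' unconfirmed and are flagged "no-rule". The MS/MS precursor must lie
#' within the isolation window (3 Da) of the annotated peak m/z.
#'
#' @param ann annotation rows for a single peak (from [annotatePeaks()])
#' @param msms an MS/MS \linkS4class{Spectrum}
#' @param rules fragment rule table (default [fragmentRules()])
#' @param fragTolDa fragment match tolerance in Da
#' @param isolationDa precursor isolation half-window in Da
#' @return \code{ann} with \code{confirmed} filled in and a
#'   \code{confirm_note} column
#' @export
confirmWithMsms <- function(ann, msms, rules = fragmentRules(),
                            fragTolDa = 0.01, isolationDa = 3) {
  stopifnot(is(msms, "Spectrum"))
  if (msms@msLevel != 2L) stop("confirmWithMsms expects an MS/MS spectrum")
  if (!nrow(ann)) return(ann)
  if (any(abs(msms@precursorMz - ann$peak_mz) > isolationDa))
    stop(sprintf("MS/MS precursor %.4f outside the %g Da isolation window",
                 msms@precursorMz, isolationDa))
  fa <- NULL
  nh3 <- monoisotopicMass(elementComposition(N = 1, H = 3))
  ann$confirm_note <- ""
  for (i in seq_len(nrow(ann))) {
    rr <- rules[rules$class == ann$class[i] &
                rules$polarity == msms@polarity, , drop = FALSE]
    if (!nrow(rr)) {
      ann$confirmed[i] <- FALSE
      ann$confirm_note[i] <- "no-rule"
      next
    }
    ok <- TRUE
    for (j in seq_len(nrow(rr))) {
      found <- switch(rr$type[j],
        fragment = .hasPeakNear(msms, rr$value[j], fragTolDa),
        neutral_loss = .hasPeakNear(msms, msms@precursorMz - rr$value[j],
                                    fragTolDa),
        acyl_loss = {
          if (is.null(fa)) fa <- .faMasses()
          any(vapply(fa, function(m)
            .hasPeakNear(msms, msms@precursorMz - m - nh3, fragTolDa),
            logical(1)))
        })
      if (!found) { ok <- FALSE; break }
    }
    ann$confirmed[i] <- ok
  }
  ann
}

#' Resolve competing annotations of one peak
#'
#' MS/MS-confirmed candidates outrank unconfirmed ones; within a tier the
#' smallest |ppm| wins; remaining ties break deterministically by
#' canonical name, then adduct.
#'
#' @param candidates annotation rows for a single peak
#' @return the single winning row
#' @export
resolveAmbiguity <- function(candidates) {
  if (!nrow(candidates)) stop("no candidates to resolve")
  conf <- candidates$confirmed
  conf[is.na(conf)] <- FALSE
  o <- order(!conf, abs(candidates$ppm), candidates$name, candidates$adduct)
  candidates[o[1], , drop = FALSE]
}

#' Read / write Mascot generic format (MGF) peak lists
#'
#' Minimal MGF support for MS/MS exchange: BEGIN IONS / END IONS blocks
#' with PEPMASS, CHARGE (sign gives polarity) and TITLE.
#'
#' @param path file path
#' @return \code{readMgf}: list of \linkS4class{Spectrum}
#' @export
readMgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  inBlock <- FALSE; mz <- intensity <- numeric(); prec <- NA_real_
  pol <- "positive"; title <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      inBlock <- TRUE; mz <- intensity <- numeric()
      prec <- NA_real_; pol <- "positive"; title <- NULL
    } else if (ln == "END IONS") {
      sp <- Spectrum(mz, intensity, polarity = pol, msLevel = 2L,
                     precursorMz = prec)
      out[[length(out) + 1L]] <- sp
      if (!is.null(title)) names(out)[length(out)] <- title
      inBlock <- FALSE
    } else if (inBlock && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln)); val <- sub("^[^=]*=", "", ln)
      if (key == "PEPMASS") prec <- as.numeric(strsplit(val, "[ \t]")[[1]][1])
      if (key == "CHARGE" && grepl("-", val, fixed = TRUE)) pol <- "negative"
      if (key == "TITLE") title <- val
    } else if (inBlock) {
      f <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      mz <- c(mz, f[1])
      intensity <- c(intensity, if (length(f) > 1) f[2] else 1)
    }
  }
  out
}

#' @rdname readMgf
#' @param spectra list of MS/MS \linkS4class{Spectrum} objects
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  nms <- names(spectra)
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    writeLines("BEGIN IONS", con)
    if (!is.null(nms) && nzchar(nms[i]))
      writeLines(paste0("TITLE=", nms[i]), con)
    writeLines(sprintf("PEPMASS=%.6f", sp@precursorMz), con)
    writeLines(paste0("CHARGE=1", if (sp@polarity == "positive") "+" else "-"),
               con)
    writeLines(sprintf("%.6f %.6f", sp@peaks$mz, sp@peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Write annotations as delimited text
#' @param ann annotation data.frame
#' @param path output TSV path
#' @export
writeAnnotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
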