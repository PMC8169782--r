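# Theoretical lipid mass database: elemental compositions at the
# sum-composition level (class + total acyl carbons : double bonds),
# monoisotopic masses, ESI adduct m/z values, and ppm-window queries.

# IUPAC monoisotopic atomic masses (Da)
.ELEMENT_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151)
.ELECTRON_MASS <- 0.00054857990907

#' Elemental composition
#'
#' A composition over the elements C, H, N, O, P as a named non-negative
#' integer vector. Sums and differences of compositions are taken
#' element-wise and must never go negative.
#'
#' @param C,H,N,O,P non-negative integer element counts
#' @return named integer vector of class \code{ElementComposition}
#' @examples
#' elementComposition(H = 2, O = 1)  # water
#' @export
elementComposition <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  x <- c(C = C, H = H, N = N, O = O, P = P)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("element counts must be non-negative integers")
  structure(as.integer(x), names = names(.ELEMENT_MASS),
            class = "ElementComposition")
}

.compAdd <- function(a, b) {
  elementComposition(C = a["C"] + b["C"], H = a["H"] + b["H"],
                     N = a["N"] + b["N"], O = a["O"] + b["O"],
                     P = a["P"] + b["P"])
}

.compSub <- function(a, b) {
  d <- unclass(a) - unclass(b)
  if (any(d < 0)) stop("composition difference would be negative")
  elementComposition(C = d["C"], H = d["H"], N = d["N"], O = d["O"],
                     P = d["P"])
}

#' Molecular formula string (Hill-like order C, H, N, O, P)
#' @param comp an \code{ElementComposition}
#' @return character scalar, e.g. "C42H82NO8P"
#' @export
formatFormula <- function(comp) {
  n <- unclass(comp)
  parts <- vapply(names(n), function(e) {
    if (n[[e]] == 0L) "" else if (n[[e]] == 1L) e else paste0(e, n[[e]])
  }, character(1))
  paste(parts, collapse = "")
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp an \code{ElementComposition}
#' @return mass in Da (0 for the empty composition)
#' @examples
#' monoisotopicMass(elementComposition(H = 2, O = 1))  # 18.010565
#' @export
monoisotopicMass <- function(comp) {
  sum(unclass(comp) * .ELEMENT_MASS)
}

# Class registry. Composition rule: for total acyl carbons C and total
# double bonds D each class formula is linear in (C, D); the rules below
# were cross-checked species-by-species against an independent
# elemental-mass calculator. nChains is the number of acyl/alkyl chains
# folded into the C:D total (for SM/Cer the sphingoid base counts as one).
.LIPID_CLASSES <- list(
  PC     = list(nChains = 2L, cRange = c(24L, 48L), dRange = c(0L, 12L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M+HCOO]-"),
  LPC    = list(nChains = 1L, cRange = c(12L, 26L), dRange = c(0L, 6L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M+HCOO]-"),
  PE     = list(nChains = 2L, cRange = c(24L, 48L), dRange = c(0L, 12L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M-H]-"),
  PS     = list(nChains = 2L, cRange = c(24L, 48L), dRange = c(0L, 12L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M-H]-"),
  PA     = list(nChains = 2L, cRange = c(24L, 48L), dRange = c(0L, 12L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M-H]-"),
  `PC-O` = list(nChains = 2L, cRange = c(24L, 48L), dRange = c(0L, 12L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M+HCOO]-"),
  `PE-O` = list(nChains = 2L, cRange = c(24L, 48L), dRange = c(0L, 12L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M-H]-"),
  SM     = list(nChains = 2L, cRange = c(24L, 48L), dRange = c(0L, 12L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M+HCOO]-"),
  Cer    = list(nChains = 2L, cRange = c(24L, 48L), dRange = c(0L, 12L),
                pos = c("[M+H]+", "[M+Na]+"), neg = "[M-H]-"),
  TG     = list(nChains = 3L, cRange = c(30L, 70L), dRange = c(0L, 15L),
                pos = c("[M+NH4]+", "[M+Na]+"), neg = character()),
  CE     = list(nChains = 1L, cRange = c(12L, 24L), dRange = c(0L, 6L),
                pos = c("[M+NH4]+", "[M+Na]+"), neg = character()),
  FA     = list(nChains = 1L, cRange = c(12L, 26L), dRange = c(0L, 6L),
                pos = character(), neg = "[M-H]-")
)

#' Supported lipid class codes
#' @return character vector of class codes
#' @export
lipidClassCodes <- function() names(.LIPID_CLASSES)

#' ESI adduct table
#'
#' Singly charged electrospray adducts and their mass deltas. The deltas
#' include the electron mass so that m/z = mass + delta (charge 1).
#'
#' @param polarity optional filter, "positive" or "negative"
#' @return data.frame with columns adduct, polarity, delta, charge
#' @export
adductTable <- function(polarity = NULL) {
  tab <- data.frame(
    adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+HCOO]-"),
    polarity = c("positive", "positive", "positive", "negative", "negative"),
    delta = c(1.00727646688,
              monoisotopicMass(elementComposition(N = 1, H = 4)) - .ELECTRON_MASS,
              22.98976928 - .ELECTRON_MASS,
              -1.00727646688,
              monoisotopicMass(elementComposition(C = 1, H = 1, O = 2)) +
                .ELECTRON_MASS),
    charge = 1L,
    stringsAsFactors = FALSE)
  if (!is.null(polarity)) tab <- tab[tab$polarity == polarity, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Elemental composition of a lipid sum composition
#'
#' Applies the class backbone rule to the total acyl carbon and double
#' bond counts. Totals fold all chains together (for SM and Cer the
#' sphingoid base is included in the totals).
#'
#' @param class lipid class code (see [lipidClassCodes()])
#' @param C total acyl/chain carbons
#' @param D total double bonds
#' @param checkRange enforce the class's configured (C, D) ranges
#' @return an \code{ElementComposition}
#' @examples
#' formatFormula(lipidComposition("PC", 34, 1))  # "C42H82NO8P"
#' @export
lipidComposition <- function(class, C, D, checkRange = TRUE) {
  cls <- .LIPID_CLASSES[[class]]
  if (is.null(cls)) stop("unknown lipid class: ", class)
  C <- as.integer(C); D <- as.integer(D)
  if (D > C %/% 2 || D < 0 || C < 1)
    stop(sprintf("invalid composition %s %d:%d (need 0 <= D <= C/2)",
                 class, C, D))
  if (checkRange &&
      (C < cls$cRange[1] || C > cls$cRange[2] ||
       D < cls$dRange[1] || D > cls$dRange[2]))
    stop(sprintf("%s %d:%d outside configured range C %d-%d, D %d-%d",
                 class, C, D, cls$cRange[1], cls$cRange[2],
                 cls$dRange[1], cls$dRange[2]))
  h <- 2L * C - 2L * D
  switch(class,
    PC      = elementComposition(C = C + 8L,  H = h + 16L, N = 1L, O = 8L,  P = 1L),
    LPC     = elementComposition(C = C + 8L,  H = h + 18L, N = 1L, O = 7L,  P = 1L),
    PE      = elementComposition(C = C + 5L,  H = h + 10L, N = 1L, O = 8L,  P = 1L),
    PS      = elementComposition(C = C + 6L,  H = h + 10L, N = 1L, O = 10L, P = 1L),
    PA      = elementComposition(C = C + 3L,  H = h + 5L,            O = 8L,  P = 1L),
    `PC-O`  = elementComposition(C = C + 8L,  H = h + 18L, N = 1L, O = 7L,  P = 1L),
    `PE-O`  = elementComposition(C = C + 5L,  H = h + 12L, N = 1L, O = 7L,  P = 1L),
    SM      = elementComposition(C = C + 5L,  H = h + 13L, N = 2L, O = 6L,  P = 1L),
    Cer     = elementComposition(C = C,       H = h + 1L,  N = 1L, O = 3L),
    TG      = elementComposition(C = C + 3L,  H = h + 2L,            O = 6L),
    CE      = elementComposition(C = C + 27L, H = h + 44L,           O = 2L),
    FA      = elementComposition(C = C,       H = h,                 O = 2L))
}

#' Canonical sum-composition lipid name
#' @param class class code
#' @param C,D total acyl carbons and double bonds
#' @return character, e.g. "PC 34:1"
#' @export
lipidName <- function(class, C, D) sprintf("%s %d:%d", class, C, D)

#' Parse lipid names into class and summed composition
#'
#' Accepts sum-composition names ("PC 34:1"), chain-annotated names with
#' underscores ("PC 16:0_20:3", "TG 18:0_18:1_18:1") and sphingolipid
#' d-notation ("SM d18:1/22:0"); chain carbons and double bonds are
#' summed into totals. Canonical names round-trip:
#' \code{parseLipidName(lipidName(cls, C, D))} recovers (cls, C, D).
#'
#' @param name character vector of lipid names
#' @return data.frame with columns name, class, C, D, nChainsStated
#' @export
parseLipidName <- function(name) {
  one <- function(nm) {
    m <- regmatches(nm, regexec("^([A-Za-z][A-Za-z-]*)[ ]+(.+)$", nm))[[1]]
    if (length(m) != 3L) stop("cannot parse lipid name: ", nm)
    cls <- m[2]
    if (!cls %in% names(.LIPID_CLASSES)) stop("unknown lipid class in: ", nm)
    toks <- strsplit(m[3], "[/_]")[[1]]
    cd <- vapply(toks, function(tk) {
      mm <- regmatches(tk, regexec("^[dt]?([0-9]+):([0-9]+)$", tk))[[1]]
      if (length(mm) != 3L) stop("cannot parse chain token '", tk, "' in ", nm)
      c(as.integer(mm[2]), as.integer(mm[3]))
    }, integer(2))
    c(C = sum(cd[1, ]), D = sum(cd[2, ]), n = length(toks))
  }
  res <- t(vapply(name, one, c(C = 0L, D = 0L, n = 0L)))
  data.frame(name = name, class = sub("[ ].*$", "", name),
             C = res[, "C"], D = res[, "D"],
             nChainsStated = res[, "n"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Explicit acyl chains stated in a lipid name
#'
#' Returns the chain tokens (e.g. "18:2") only when the name spells them
#' out ("PC 16:0_18:2", "SM d18:1/22:0"); for single-chain classes (LPC,
#' CE, FA) the one stated composition is the chain. Multi-chain
#' sum-composition names ("PC 34:1") yield an empty vector since their
#' chains are not resolvable.
#'
#' @param name one lipid name
#' @return character vector of chain tokens (possibly empty)
#' @export
lipidChains <- function(name) {
  cls <- sub("[ ].*$", "", name)
  body <- sub("^[A-Za-z][A-Za-z-]*[ ]+", "", name)
  toks <- strsplit(body, "[/_]")[[1]]
  nChains <- if (cls %in% names(.LIPID_CLASSES))
    .LIPID_CLASSES[[cls]]$nChains else NA_integer_
  if (length(toks) < 2L && !identical(nChains, 1L)) return(character())
  sub("^[dt]", "", toks)
}

#' Build the theoretical lipid ion database
#'
#' Enumerates every (class, C, D, adduct) combination allowed by the
#' class composition rules: even total acyl carbons within the class C
#' range, double bonds within the class D range (and at most C/2), and
#' the class's adducts for the requested polarity. Ions are deduplicated
#' and sorted by m/z.
#'
#' @param classes class codes to enumerate (default: all)
#' @param polarity "positive" or "negative"
#' @param cRange,dRange optional length-2 overrides applied to every class
#' @param adducts optional adduct-name subset
#' @param mzRange optional acquisition window; ions outside are dropped
#' @return a \linkS4class{LipidDatabase}
#' @examples
#' db <- buildLipidDatabase("PC", cRange = c(34, 34), dRange = c(0, 1),
#'                          adducts = "[M+H]+")
#' ionsOf(db)
#' @export
buildLipidDatabase <- function(classes = lipidClassCodes(),
                               polarity = c("positive", "negative"),
                               cRange = NULL, dRange = NULL,
                               adducts = NULL, mzRange = NULL) {
  polarity <- match.arg(polarity)
  if (!length(classes)) stop("no lipid classes given")
  unknown <- setdiff(classes, names(.LIPID_CLASSES))
  if (length(unknown)) stop("unknown classes: ", paste(unknown, collapse = ", "))
  atab <- adductTable(polarity)
  if (!is.null(adducts)) {
    bad <- setdiff(adducts, adductTable()$adduct)
    if (length(bad)) stop("unknown adducts: ", paste(bad, collapse = ", "))
    atab <- atab[atab$adduct %in% adducts, , drop = FALSE]
  }
  rows <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    cc <- classes[k]
    cls <- .LIPID_CLASSES[[cc]]
    cr <- if (is.null(cRange)) cls$cRange else as.integer(cRange)
    dr <- if (is.null(dRange)) cls$dRange else as.integer(dRange)
    cu <- seq.int(cr[1] + cr[1] %% 2L, cr[2], by = 2L)  # even totals only
    adu <- atab[atab$adduct %in% cls[[substr(polarity, 1, 3)]], , drop = FALSE]
    if (!nrow(adu) || !length(cu)) next
    grid <- expand.grid(C = cu, D = seq.int(dr[1], dr[2]),
                        ai = seq_len(nrow(adu)))
    grid <- grid[grid$D <= grid$C %/% 2, , drop = FALSE]
    if (!nrow(grid)) next
    comp <- lapply(seq_len(nrow(grid)), function(i)
      lipidComposition(cc, grid$C[i], grid$D[i], checkRange = FALSE))
    mass <- vapply(comp, monoisotopicMass, numeric(1))
    rows[[k]] <- data.frame(
      name = lipidName(cc, grid$C, grid$D), class = cc,
      C = grid$C, D = grid$D,
      formula = vapply(comp, formatFormula, character(1)),
      mass = mass,
      adduct = adu$adduct[grid$ai], polarity = polarity,
      mz = mass + adu$delta[grid$ai],
      stringsAsFactors = FALSE)
  }
  ions <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(ions) || !nrow(ions))
    stop("database enumeration is empty; check classes/ranges/adducts")
  if (!is.null(mzRange))
    ions <- ions[ions$mz >= mzRange[1] & ions$mz <= mzRange[2], , drop = FALSE]
  if (!nrow(ions)) stop("no ions inside the requested m/z range")
  ions <- ions[!duplicated(paste(ions$name, ions$adduct)), , drop = FALSE]
  ions <- ions[order(ions$mz, ions$name, ions$adduct), , drop = FALSE]
  rownames(ions) <- NULL
  new("LipidDatabase", ions = ions,
      params = list(classes = sort(classes), polarity = polarity,
                    cRange = cRange, dRange = dRange, adducts = adducts,
                    mzRange = mzRange))
}

#' Ion table of a lipid database
#' @param db a \linkS4class{LipidDatabase}
#' @return the sorted data.frame of theoretical ions
#' @export
ionsOf <- function(db) db@ions

#' Signed parts-per-million mass error
#'
#' @param observed observed m/z
#' @param theoretical theoretical m/z (> 0)
#' @return 1e6 * (observed - theoretical) / theoretical
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

#' Query a lipid database inside a ppm window
#'
#' Returns every theoretical ion whose |ppm error| relative to the query
#' m/z is at most \code{tolPpm} (window edges inclusive), ordered by
#' increasing |ppm| with ties broken by canonical name.
#'
#' @param db a \linkS4class{LipidDatabase}
#' @param mz query m/z
#' @param tolPpm tolerance in ppm (> 0)
#' @return data.frame of matching ions with a \code{ppm} column (possibly
#'   zero rows)
#' @export
setMethod("queryMz", "LipidDatabase", function(db, mz, tolPpm = 10) {
  stopifnot(tolPpm > 0, length(mz) == 1L)
  ions <- db@ions
  if (!nrow(ions)) stop("empty database")
  lo <- mz / (1 + tolPpm * 1e-6)
  hi <- mz / (1 - tolPpm * 1e-6)
  i1 <- findInterval(lo, ions$mz, left.open = TRUE) + 1L
  i2 <- findInterval(hi, ions$mz)
  if (i1 > i2) return(cbind(ions[0, , drop = FALSE], ppm = numeric()))
  hit <- ions[i1:i2, , drop = FALSE]
  hit$ppm <- ppmError(mz, hit$mz)
  hit <- hit[abs(hit$ppm) <= tolPpm, , drop = FALSE]
  hit <- hit[order(abs(hit$ppm), hit$name, hit$adduct), , drop = FALSE]
  rownames(hit) <- NULL
  hit
})

#' @describeIn buildLipidDatabase write a database as delimited text
#'   (TSV with columns name, class, C, D, formula, mass, adduct,
#'   polarity, mz) or JSON.
#' @param db a \linkS4class{LipidDatabase}
#' @param path output file
#' @param format "tsv" or "json"
#' @export
writeLipidDatabase <- function(db, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(db@ions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(params = db@params, ions = db@ions), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @describeIn buildLipidDatabase read a database written by
#'   \code{writeLipidDatabase}.
#' @export
readLipidDatabase <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ions <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    params <- list(source = path)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ions <- as.data.frame(obj$ions, stringsAsFactors = FALSE)
    params <- obj$params
  }
  ions <- ions[order(ions$mz, ions$name, ions$adduct), , drop = FALSE]
  rownames(ions) <- NULL
  new("LipidDatabase", ions = ions, params = params)
}

setMethod("show", "LipidDatabase", function(object) {
  ions <- object@ions
  cat("LipidDatabase:", nrow(ions), "theoretical ions (",
      object@params$polarity %||% "?", "mode )\n")
  cat("  classes:", paste(sort(unique(ions$class)), collapse = ", "), "\n")
  cat("  m/z range:", sprintf("%.4f - %.4f", min(ions$mz), max(ions$mz)), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
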