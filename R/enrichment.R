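# Over-representation analysis of significant lipids against a bundled
# lipid-class pathway map (a compact stand-in for a curated pathway
# library) by exact hypergeometric test with BH adjustment.

#' Exact upper-tail hypergeometric p-value
#'
#' P(X >= k) when drawing n items from a background of N containing K
#' pathway members.
#'
#' @param k significant lipids in the pathway
#' @param K background lipids in the pathway
#' @param n significant lipids in total
#' @param N background lipids in total
#' @return exact upper-tail probability
#' @examples
#' hypergeometricP(4, 5, 6, 20)  # 540 / 38760
#' @export
hypergeometricP <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric bounds: need 0 <= k <= min(K, n), K,n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bundled lipid pathway map
#'
#' Compact lipid-class pathway definitions: glycerophospholipid
#' metabolism (PC, LPC, PE, PS, PA), sphingolipid metabolism (SM, Cer),
#' ether lipid metabolism (PC-O, PE-O), glycerolipid metabolism (TG),
#' and linoleic acid metabolism (species with an explicit 18:2 acyl
#' chain; sum-composition names, whose chains are not resolvable, are
#' excluded from that pathway).
#'
#' @return named list of pathway definitions (\code{classes} and
#'   optional \code{requiresChain})
#' @export
defaultPathways <- function() {
  list(
    "Glycerophospholipid metabolism" =
      list(classes = c("PC", "LPC", "PE", "PS", "PA")),
    "Sphingolipid metabolism" = list(classes = c("SM", "Cer")),
    "Ether lipid metabolism" = list(classes = c("PC-O", "PE-O")),
    "Glycerolipid metabolism" = list(classes = "TG"),
    "Linoleic acid metabolism" =
      list(classes = c("PC", "LPC", "PE", "PS", "PA", "PC-O", "PE-O",
                       "SM", "Cer", "TG", "CE", "FA"),
           requiresChain = "18:2"))
}

.inPathway <- function(names, pathway) {
  cls <- sub("[ ].*$", "", names)
  hit <- cls %in% pathway$classes
  if (!is.null(pathway$requiresChain)) {
    hit <- hit & vapply(names, function(nm)
      pathway$requiresChain %in% lipidChains(nm), logical(1))
  }
  hit
}

#' Lipid-set over-representation analysis
#'
#' Tests each pathway for enrichment of the significant lipid set
#' against the background (all annotated lipids analyzed) by exact
#' hypergeometric upper-tail test; results are BH-adjusted across
#' pathways and sorted by p.
#'
#' @param significant character vector of significant lipid names (must
#'   be a subset of \code{background})
#' @param background character vector of all analyzed lipid names
#' @param pathways pathway map (default [defaultPathways()])
#' @return data.frame: pathway, k, K, n, N, p, p_adj; pathways with no
#'   background members are dropped
#' @export
enrichLipidSets <- function(significant, background,
                            pathways = defaultPathways()) {
  significant <- unique(significant)
  background <- unique(background)
  if (!length(background)) stop("background set is empty")
  extra <- setdiff(significant, background)
  if (length(extra))
    stop("significant lipids not in background: ",
         paste(extra, collapse = ", "))
  N <- length(background); n <- length(significant)
  rows <- lapply(names(pathways), function(pw) {
    memberBg <- .inPathway(background, pathways[[pw]])
    K <- sum(memberBg)
    if (K == 0) return(NULL)
    k <- sum(significant %in% background[memberBg])
    data.frame(pathway = pw, k = k, K = K, n = n, N = N,
               p = hypergeometricP(k, K, n, N), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(pathway = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric()))
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res <- res[order(res$p, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}
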