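## The structural conservation rate: mean absolute difference of structural
## profiles over all unordered pairs of a TF's binding sites, normalized per
## informative profile position, globally and per position.

#' Absolute difference of two structural profiles
#'
#' @param pA,pB equal-length numeric profiles under the same property
#' @return numeric vector `|pA - pB|`; `NA` where either side is missing
#' @export
pairwiseAbsDiff <- function(pA, pB) {
  if (length(pA) != length(pB)) stop("profile length mismatch: ",
                                     length(pA), " vs ", length(pB))
  abs(pA - pB)
}

## profile matrix of a site set (n x P)
.siteProfileMatrix <- function(set, table) {
  seqs <- as.character(set@sites)
  codes <- t(vapply(seqs, .seqCodes, integer(nchar(seqs[1])), USE.NAMES = FALSE))
  if (ncol(codes) < table@k)
    stop("sites shorter than table word length k = ", table@k)
  .profileMatrix(codes, table)
}

## shared implementation: global and per-position rates from a profile matrix
.rateFromProfiles <- function(X) {
  n <- nrow(X)
  nPairs <- n * (n - 1) / 2
  if (!anyNA(X)) {
    perPos <- .colPairMeanAbsDiff(X)
    return(list(value = mean(perPos), perPosition = perPos, nPairs = nPairs))
  }
  ## missing-data path: pairwise means over co-informative positions only
  P <- ncol(X)
  posSum <- numeric(P)
  posCnt <- integer(P)
  pairMeans <- numeric(nPairs)
  keep <- logical(nPairs)
  idx <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      idx <- idx + 1L
      d <- abs(X[i, ] - X[j, ])
      ok <- !is.na(d)
      if (any(ok)) {
        pairMeans[idx] <- mean(d[ok])
        keep[idx] <- TRUE
        posSum[ok] <- posSum[ok] + d[ok]
        posCnt[ok] <- posCnt[ok] + 1L
      }
    }
  }
  if (!all(keep))
    warning(sum(!keep), " site pair(s) with zero co-informative positions excluded")
  if (!any(keep)) stop("all site pairs excluded: no co-informative positions")
  perPos <- posSum / posCnt
  perPos[posCnt == 0L] <- NA_real_
  list(value = mean(pairMeans[keep]), perPosition = perPos, nPairs = sum(keep))
}

#' Structural conservation rate of a site set
#'
#' For every unordered pair of sites, the absolute difference of their
#' structural profiles is averaged over co-informative positions; the global
#' rate is the mean of these pair means, and the per-position rate at i is
#' the mean absolute difference at profile position i over the pairs
#' informative there. Normalization is per *profile* position (L-1, L-2 or
#' L entries depending on the table), which makes rates comparable across
#' word lengths and makes the global rate equal the mean of the per-position
#' rates on clean sites. Low rates mean high structural conservation.
#'
#' @param set a [SiteSet-class] with at least 2 sites
#' @param table a [PropertyTable-class]
#' @return a [ConservationRate-class]
#' @export
conservationRate <- function(set, table) {
  if (nSites(set) < 2) stop("insufficient sites: need at least 2, got ", nSites(set))
  r <- .rateFromProfiles(.siteProfileMatrix(set, table))
  new("ConservationRate", value = r$value, nPairs = as.integer(r$nPairs),
      perPosition = r$perPosition, property = table@name)
}

#' Per-position structural conservation rates
#'
#' @inheritParams conservationRate
#' @return numeric vector of per-position rates (profile coordinates)
#' @export
positionalRates <- function(set, table) {
  conservationRate(set, table)@perPosition
}
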