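## Correlating 8-mer structural levels with protein-binding-microarray
## binding affinities.

#' Structural levels of all k-mers
#'
#' Computes the structural level of every DNA k-mer under one property
#' table (vectorized; the 65,536 8-mers take well under a second).
#'
#' @param table a [PropertyTable-class]
#' @param k word length (default 8, the protein-binding-microarray word
#'   size); must be at least the table's word length
#' @return named numeric vector of levels, one per k-mer
#' @export
kmerStructuralLevels <- function(table, k = 8) {
  if (!.isWholeNumber(k) || k < table@k || k > 12)
    stop("k must be an integer in ", table@k, "..12")
  n <- 4^k
  codes <- matrix(0L, n, k)
  for (j in seq_len(k)) codes[, j] <- rep(rep(1:4, each = 4^(k - j)), length.out = n)
  X <- .profileMatrix(codes, table)
  stats::setNames(rowMeans(X), .allKmers(k))
}

#' Correlate top-affinity 8-mers with structural levels
#'
#' Ranks 8-mers by binding affinity (ties broken lexicographically), keeps
#' the `topN` highest-affinity words to control for nonspecific binding,
#' and computes the Pearson correlation between affinity and structural
#' level with a two-sided t-test p-value (n - 2 degrees of freedom). The
#' pair is flagged significant when |r| > 0.1 and p < 0.05. A negative r
#' means the property inhibits binding, a positive r that it facilitates
#' binding.
#'
#' @param affinities named numeric vector of 8-mer affinity scores, as
#'   returned by [readAffinityTable()]
#' @param table a [PropertyTable-class]
#' @param topN affinity-rank cutoff (default 500)
#' @return data.frame row: `tf`, `property`, `r`, `pValue`, `n`, `topN`,
#'   `significant`
#' @export
topAffinityCorrelation <- function(affinities, table, topN = 500) {
  if (!.isWholeNumber(topN) || topN < 3) stop("topN must be an integer >= 3")
  kmer <- names(affinities)
  if (is.null(kmer) || !all(grepl("^[ACGT]{8}$", kmer)))
    stop("affinities must be named by ACGT 8-mers")
  ord <- order(-affinities, kmer)
  top <- ord[seq_len(min(topN, length(affinities)))]
  x <- unname(affinities[top])
  y <- vapply(kmer[top], function(w) as.numeric(structuralLevel(w, table)), numeric(1))
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: fewer than 3 usable points or zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  p <- ct$p.value
  data.frame(tf = ifelse(is.null(attr(affinities, "tfName")), NA_character_,
                         attr(affinities, "tfName")),
             property = table@name, r = r, pValue = p, n = length(x),
             topN = topN, significant = abs(r) > 0.1 & p < 0.05,
             stringsAsFactors = FALSE)
}
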