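## Permutation null models: PWM construction, PWM-conditioned site
## resampling, shuffled-table nulls, empirical p-values, Bonferroni.

#' Build the position weight matrix of a site set
#'
#' Per-position base counts and frequencies, no pseudocounts. Sites must be
#' ACGT-only (ambiguous sites are dropped at load time by
#' [readSiteTable()]).
#'
#' @param set a [SiteSet-class]
#' @return a [SitePWM-class]
#' @export
buildPWM <- function(set) {
  if (nSites(set) < 1) stop("empty site set")
  cm <- Biostrings::consensusMatrix(set@sites, baseOnly = TRUE)
  if (sum(cm["other", ]) > 0)
    stop("non-ACGT characters in sites of '", set@tfName, "'")
  counts <- t(cm[.BASES, , drop = FALSE])
  storage.mode(counts) <- "integer"
  colnames(counts) <- .BASES
  new("SitePWM", counts = counts, freqs = counts / nSites(set),
      nSites = nSites(set))
}

#' Information content of a PWM
#'
#' \eqn{\sum_i (2 + \sum_b f_{ib} \log_2 f_{ib})} bits; 0 log 0 is taken
#' as 0. Ranges from 0 (uniform) to 2 bits per position (consensus).
#'
#' @param pwm a [SitePWM-class]
#' @return information content in bits
#' @export
informationContent <- function(pwm) {
  f <- pwm@freqs
  fl <- f * log2(f)
  fl[f == 0] <- 0
  sum(2 + rowSums(fl))
}

## n x L base-code matrix sampled column-wise from PWM rows
.samplePWMCodes <- function(pwm, n) {
  L <- nrow(pwm@freqs)
  m <- matrix(0L, n, L)
  for (i in seq_len(L)) m[, i] <- sample.int(4L, n, replace = TRUE, prob = pwm@freqs[i, ])
  m
}

#' Sample a random site set from a PWM
#'
#' Draws each position independently from the PWM's per-position base
#' frequencies, producing random sites whose expected sequence conservation
#' (PWM, information content) matches the real sites. Uses the current RNG
#' state; call `set.seed()` for reproducibility.
#'
#' @param pwm a [SitePWM-class]
#' @param n number of sites to draw
#' @param tfName name for the sampled set
#' @return a [SiteSet-class]
#' @export
sampleSiteSet <- function(pwm, n, tfName = "sampled") {
  codes <- .samplePWMCodes(pwm, n)
  seqs <- apply(codes, 1, .codesToSeq)
  SiteSet(tfName, seqs)
}

#' Empirical permutation p-value
#'
#' Add-one convention: lower tail p = (#\{null <= real\} + 1) / (N + 1),
#' upper tail with >=. Ties count toward the extreme tail (conservative);
#' the minimum attainable p is 1/(N+1), never 0.
#'
#' @param realStat observed statistic
#' @param nullStats numeric vector of N permutation statistics
#' @param tail `"lower"` (small statistic = extreme; the conservation-rate
#'   convention) or `"upper"`
#' @return p-value in (0, 1]
#' @export
empiricalPValue <- function(realStat, nullStats, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (length(nullStats) == 0) stop("empty null distribution")
  r <- if (tail == "lower") sum(nullStats <= realStat) else sum(nullStats >= realStat)
  (r + 1) / (length(nullStats) + 1)
}

#' Bonferroni correction
#'
#' @param p p-value(s)
#' @param m family size
#' @return `min(1, p * m)`, vectorized over `p`
#' @export
bonferroniCorrect <- function(p, m) {
  if (!.isWholeNumber(m) || m < 1) stop("family size m must be a positive integer")
  pmin(1, p * m)
}

#' PWM-resampled null test of structural conservation
#'
#' Compares the real conservation rate of a site set with rates of `nPerm`
#' random site sets drawn from the real PWM (sequence conservation held
#' fixed, structure randomized). Lower-tail empirical p: a small p means
#' the real sites are more structurally conserved than their sequence
#' conservation implies.
#'
#' @param set a [SiteSet-class]
#' @param table a [PropertyTable-class]
#' @param nPerm number of randomized site sets (the analysis default is
#'   10000)
#' @return list with `realStat`, `nullStats`, `pValue`, `nPerm`
#' @export
pwmNullTest <- function(set, table, nPerm = 10000) {
  pwm <- buildPWM(set)  # errors on ambiguous bases

  real <- conservationRate(set, table)@value
  n <- nSites(set)
  nulls <- vapply(seq_len(nPerm), function(j) {
    X <- .profileMatrix(.samplePWMCodes(pwm, n), table)
    mean(.colPairMeanAbsDiff(X))
  }, numeric(1))
  list(realStat = real, nullStats = nulls,
       pValue = empiricalPValue(real, nulls, "lower"), nPerm = nPerm)
}

#' Shuffled-table null test of structural conservation
#'
#' Compares the real conservation rate with rates of the same sites scored
#' under `nPerm` tables whose parametric values were randomly permuted among
#' reverse-complement k-mer classes. A small lower-tail p means conservation
#' depends on the property's true value assignment, not merely on sequence
#' similarity.
#'
#' @inheritParams pwmNullTest
#' @export
shuffledTableNullTest <- function(set, table, nPerm = 10000) {
  if (table@positional)
    stop("unsupported shuffle: positional table '", table@name, "'")
  real <- conservationRate(set, table)@value
  seqs <- as.character(set@sites)
  codes <- t(vapply(seqs, .seqCodes, integer(nchar(seqs[1])), USE.NAMES = FALSE))
  if (anyNA(codes)) stop("sites contain ambiguous bases; null tests need ACGT-only sites")
  idx <- .windowIndex(codes, table@k)
  n <- nrow(codes)
  ## permute values among RC classes directly on the lookup vector
  classes <- rcClasses(table@k)
  classOf <- integer(4^table@k)
  for (i in seq_along(classes)) classOf[match(classes[[i]], .allKmers(table@k))] <- i
  classVals <- table@values[names(classes), 1]
  nulls <- vapply(seq_len(nPerm), function(j) {
    lut <- classVals[sample.int(length(classVals))][classOf]
    X <- matrix(lut[idx], n)
    mean(.colPairMeanAbsDiff(X))
  }, numeric(1))
  list(realStat = real, nullStats = nulls,
       pValue = empiricalPValue(real, nulls, "lower"), nPerm = nPerm)
}
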