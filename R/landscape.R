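## The three-filter landscape pipeline:
##   filter 1: real rate vs PWM-resampled random site sets (sequence
##             conservation held fixed)
##   filter 2: real rate vs shuffled property tables (dependence on the true
##             value assignment)
##   filter 3: |structural level| of sites vs +/- flankBp flanking regions
##             (one-sided Mann-Whitney)
## plus per-position conservation analysis of the survivors.

#' One-sided Mann-Whitney U test
#'
#' Thin wrapper over [stats::wilcox.test()] used by the flank comparison:
#' exact enumeration for small tie-free samples, normal approximation with
#' tie correction otherwise. Ties on the boundary count toward the extreme
#' tail.
#'
#' @param x,y numeric samples
#' @param alternative `"greater"` tests whether `x` is stochastically
#'   higher than `y`
#' @return p-value
#' @export
mannWhitneyU <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))$p.value
}

## |structural level| of every site and of its pooled flanks.
## Flank observation per site: the two segment levels combined, weighted by
## their informative profile positions; sites whose flanks yield no
## informative position are dropped (flagged in `kept`).
.siteFlankLevels <- function(set, table, genome, flankBp = 30) {
  if (is.null(set@coords))
    stop("sites lack genomic coordinates; supply a coordinate table to run the flank test")
  sc <- set@coords
  chroms <- as.character(GenomicRanges::seqnames(sc))
  starts <- GenomicRanges::start(sc) - 1L
  ends <- GenomicRanges::end(sc)
  n <- length(sc)
  siteLev <- numeric(n)
  flankLev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    siteLev[i] <- abs(structuralLevel(as.character(set@sites[[i]]), table))
    len <- length(genome[[chroms[i]]])
    segs <- list(c(max(0L, starts[i] - flankBp), starts[i]),
                 c(ends[i], min(len, ends[i] + flankBp)))
    lv <- c(); wt <- c()
    for (s in segs) {
      if (s[2] - s[1] >= table@k || (table@positional && s[2] - s[1] >= 3)) {
        seq <- fetchSequence(genome, chroms[i], s[1], s[2])
        l <- tryCatch(structuralLevel(seq, table), error = function(e) NULL)
        if (!is.null(l)) { lv <- c(lv, as.numeric(l)); wt <- c(wt, attr(l, "nUsed")) }
      }
    }
    if (length(lv)) flankLev[i] <- abs(sum(lv * wt) / sum(wt))
  }
  kept <- !is.na(flankLev)
  list(siteLevels = siteLev, flankLevels = flankLev, kept = kept)
}

#' Flank comparison test (filter 3 statistic)
#'
#' Tests whether binding sites have higher absolute structural levels than
#' their flanking regions (`flankBp` upstream and downstream, site
#' excluded, truncated at chromosome ends), via a one-sided Mann-Whitney U
#' test. Sites whose flanks contain no informative profile position are
#' dropped from the test.
#'
#' @param set a [SiteSet-class] with coordinates
#' @param table a [PropertyTable-class]
#' @param genome a [Biostrings::DNAStringSet]
#' @param flankBp flank length in bp on each side (default 30)
#' @return list with `pValue`, `siteLevels`, `flankLevels`
#' @export
flankComparisonTest <- function(set, table, genome, flankBp = 30) {
  lv <- .siteFlankLevels(set, table, genome, flankBp)
  if (!any(lv$kept)) stop("no site has informative flanking sequence")
  p <- mannWhitneyU(lv$siteLevels[lv$kept], lv$flankLevels[lv$kept], "greater")
  list(pValue = p, siteLevels = lv$siteLevels[lv$kept],
       flankLevels = lv$flankLevels[lv$kept])
}

#' Filter 1: PWM-resampled null over all TF-property pairs
#'
#' For every TF x property pair, computes the real conservation rate and an
#' empirical lower-tail p-value against `nPerm` random site sets drawn from
#' the TF's PWM. Null site sets are shared across properties within a TF.
#' A pair passes when the Bonferroni-corrected p (family = number of
#' properties) is below `alpha`.
#'
#' @param sets named list of [SiteSet-class] (already restricted to TFs
#'   with enough sites)
#' @param compendium a [PropertyCompendium-class]
#' @param nPerm permutations per TF (analysis default 10000)
#' @param alpha significance level (default 0.05)
#' @return data.frame, one row per TF x property
#' @export
runFilter1 <- function(sets, compendium, nPerm = 10000, alpha = 0.05) {
  m <- length(compendium)
  rows <- lapply(sets, function(set) {
    pwm <- buildPWM(set)
    n <- nSites(set)
    real <- vapply(compendium, function(tb) conservationRate(set, tb)@value, numeric(1))
    nulls <- matrix(0, nPerm, m)
    for (j in seq_len(nPerm)) {
      codes <- .samplePWMCodes(pwm, n)
      nulls[j, ] <- vapply(compendium, function(tb)
        mean(.colPairMeanAbsDiff(.profileMatrix(codes, tb))), numeric(1))
    }
    p <- vapply(seq_len(m), function(i) empiricalPValue(real[i], nulls[, i], "lower"),
                numeric(1))
    data.frame(tf = set@tfName, property = names(compendium),
               rate = unname(real), nPairs = n * (n - 1) / 2,
               pPwmNull = p, passed1 = bonferroniCorrect(p, m) < alpha,
               m1 = m, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Filter 2: shuffled-table null over filter-1 survivors
#'
#' Adds `pShuffleNull` / `passed2` to the filter-1 survivors, testing each
#' against `nPerm` tables with values permuted among reverse-complement
#' k-mer classes. The Bonferroni family is the number of surviving pairs.
#' Positional-table pairs cannot be shuffled; they are flagged
#' (`shuffleSkipped`) and conservatively not passed.
#'
#' @param landscape data.frame from [runFilter1()]
#' @inheritParams runFilter1
#' @return the landscape with filter-2 columns added
#' @export
runFilter2 <- function(landscape, sets, compendium, nPerm = 10000, alpha = 0.05) {
  landscape$pShuffleNull <- NA_real_
  landscape$shuffleSkipped <- FALSE
  landscape$passed2 <- FALSE
  surv <- which(landscape$passed1)
  m <- length(surv)
  landscape$m2 <- m
  for (i in surv) {
    tb <- compendium[[landscape$property[i]]]
    if (tb@positional) {
      message("filter 2: shuffle unsupported for positional table '", tb@name,
              "' (pair ", landscape$tf[i], " x ", tb@name, " skipped)")
      landscape$shuffleSkipped[i] <- TRUE
      next
    }
    res <- shuffledTableNullTest(sets[[landscape$tf[i]]], tb, nPerm)
    landscape$pShuffleNull[i] <- res$pValue
    landscape$passed2[i] <- bonferroniCorrect(res$pValue, m) < alpha
  }
  landscape
}

#' Filter 3: flank comparison over filter-2 survivors
#'
#' Adds `pFlank` / `passed3`, testing whether each surviving pair's sites
#' have higher absolute structural levels than their flanks. Bonferroni
#' family = number of filter-2 survivors.
#'
#' @param landscape data.frame from [runFilter2()]
#' @param genome a [Biostrings::DNAStringSet]
#' @param flankBp flank length in bp (default 30)
#' @inheritParams runFilter1
#' @return the landscape with filter-3 columns added
#' @export
runFilter3 <- function(landscape, sets, genome, compendium, flankBp = 30, alpha = 0.05) {
  landscape$pFlank <- NA_real_
  landscape$passed3 <- FALSE
  surv <- which(landscape$passed2)
  m <- length(surv)
  landscape$m3 <- m
  for (i in surv) {
    tb <- compendium[[landscape$property[i]]]
    res <- flankComparisonTest(sets[[landscape$tf[i]]], tb, genome, flankBp)
    landscape$pFlank[i] <- res$pValue
    landscape$passed3[i] <- bonferroniCorrect(res$pValue, m) < alpha
  }
  landscape
}

#' Per-position conservation analysis
#'
#' Compares the real per-position conservation rate with the same
#' position's rates in `nPerm` PWM-resampled site sets (lower tail).
#' Bonferroni family = profile length. Positions are reported 1-based in
#' profile coordinates.
#'
#' @param set a [SiteSet-class]
#' @param table a [PropertyTable-class]
#' @param nPerm permutations (analysis default 10000)
#' @param alpha significance level
#' @return list with `pValues`, `significant` (1-based positions),
#'   `realRates`, `nullMean`, `nullSd`
#' @export
positionalAnalysis <- function(set, table, nPerm = 10000, alpha = 0.05) {
  pwm <- buildPWM(set)
  n <- nSites(set)
  real <- positionalRates(set, table)
  P <- length(real)
  nulls <- matrix(0, nPerm, P)
  for (j in seq_len(nPerm))
    nulls[j, ] <- .colPairMeanAbsDiff(.profileMatrix(.samplePWMCodes(pwm, n), table))
  p <- vapply(seq_len(P), function(i) empiricalPValue(real[i], nulls[, i], "lower"),
              numeric(1))
  list(pValues = p, significant = which(bonferroniCorrect(p, P) < alpha),
       realRates = real, nullMean = colMeans(nulls), nullSd = apply(nulls, 2, stats::sd))
}

#' Build the TF x structure landscape
#'
#' Runs the three filters in order on a cohort of site sets, then the
#' per-position analysis on the pairs surviving all three, and returns the
#' full landscape table, a TF x property pass/fail matrix and the
#' positional results.
#'
#' @param sets named list of [SiteSet-class]
#' @param compendium a [PropertyCompendium-class]
#' @param genome a [Biostrings::DNAStringSet]; may be `NULL` only when no
#'   pair survives filter 2
#' @param nPerm permutations for filters 1-2 and the positional analysis
#' @param alpha significance level
#' @param flankBp flank length for filter 3
#' @param minSites if non-`NULL`, apply [filterByMinSites()] first
#' @param seed optional integer seed for end-to-end reproducibility
#' @return list with `landscape` (data.frame), `matrix` (logical TF x
#'   property), `positional` (data.frame), `params`
#' @export
buildLandscape <- function(sets, compendium, genome = NULL, nPerm = 10000,
                           alpha = 0.05, flankBp = 30, minSites = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(minSites)) sets <- filterByMinSites(sets, minSites)
  if (length(sets) == 0) stop("no site sets left to analyze")
  names(sets) <- vapply(sets, tfName, character(1))
  land <- runFilter1(sets, compendium, nPerm, alpha)
  land <- runFilter2(land, sets, compendium, nPerm, alpha)
  if (any(land$passed2)) {
    if (is.null(genome))
      stop("pairs survive filter 2 but no genome was supplied for the flank test")
    land <- runFilter3(land, sets, genome, compendium, flankBp, alpha)
  } else {
    land$pFlank <- NA_real_
    land$passed3 <- FALSE
    land$m3 <- 0L
  }
  posRows <- list()
  for (i in which(land$passed3)) {
    pa <- positionalAnalysis(sets[[land$tf[i]]], compendium[[land$property[i]]],
                             nPerm, alpha)
    posRows[[length(posRows) + 1]] <- data.frame(
      tf = land$tf[i], property = land$property[i],
      position = seq_along(pa$realRates), realRate = pa$realRates,
      nullMean = pa$nullMean, pValue = pa$pValues,
      significant = seq_along(pa$realRates) %in% pa$significant,
      stringsAsFactors = FALSE)
  }
  positional <- if (length(posRows)) do.call(rbind, posRows) else
    data.frame(tf = character(), property = character(), position = integer(),
               realRate = numeric(), nullMean = numeric(), pValue = numeric(),
               significant = logical())
  tfs <- vapply(sets, tfName, character(1))
  mat <- matrix(FALSE, length(tfs), length(compendium),
                dimnames = list(tfs, names(compendium)))
  for (i in which(land$passed3)) mat[land$tf[i], land$property[i]] <- TRUE
  list(landscape = land, matrix = mat, positional = positional,
       params = list(nPerm = nPerm, alpha = alpha, flankBp = flankBp,
                     minSites = minSites, seed = seed,
                     familySizes = c(filter1 = land$m1[1],
                                     filter2 = land$m2[1],
                                     filter3 = land$m3[1])))
}

#' Write landscape results to a directory
#'
#' Emits `landscape.tsv` (one row per TF x property with all p-values and
#' pass flags), `matrix.tsv` (TF x property pass matrix), `positional.tsv`
#' and `run.log` (parameters and family sizes).
#'
#' @param result list from [buildLandscape()]
#' @param dir output directory (created if needed)
#' @export
writeLandscape <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$landscape, file.path(dir, "landscape.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(tf = rownames(result$matrix),
                                result$matrix, check.names = FALSE),
                     file.path(dir, "matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$positional, file.path(dir, "positional.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- result$params
  writeLines(c(
    sprintf("nPerm\t%d", p$nPerm), sprintf("alpha\t%g", p$alpha),
    sprintf("flankBp\t%d", p$flankBp),
    sprintf("minSites\t%s", ifelse(is.null(p$minSites), "NA", p$minSites)),
    sprintf("seed\t%s", ifelse(is.null(p$seed), "NA", p$seed)),
    sprintf("family_filter1\t%d", p$familySizes[["filter1"]]),
    sprintf("family_filter2\t%d", p$familySizes[["filter2"]]),
    sprintf("family_filter3\t%d", p$familySizes[["filter3"]])),
    file.path(dir, "run.log"))
  invisible(dir)
}
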