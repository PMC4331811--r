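## Shared fixtures: toy property tables, the synthetic benchmark cohort,
## and slow-but-obvious oracles kept independent of the package internals.

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

randomSeq <- function(L, alphabet = BASES) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

## dinucleotide table from one value per RC class
## (class order AA AC AG AT CA CC CG GA GC TA)
toyClassTable <- function(name, classVals, category = "conformational") {
  cls <- rcClasses(2)
  v <- numeric(16)
  names(v) <- enumerateKmers(2)
  for (i in seq_along(cls)) v[cls[[i]]] <- classVals[i]
  PropertyTable(name, v, category = category)
}

## two-entry toy table used by the worked examples (all other values 0)
toyPairTable <- function(vAA = 0, vAT = 1) {
  v <- numeric(16)
  names(v) <- enumerateKmers(2)
  v["AA"] <- vAA; v["TT"] <- vAA
  v["AT"] <- vAT
  PropertyTable("toy", v)
}

## ---- benchmark cohort: two planted TF-property constraints ----
## Planted properties use four reverse-complement classes sharing one
## extreme value (structural synonymy) including a recombination-breaker
## class inside the dominant letter pair; all other class values are
## distinct and spaced >= 2.
cohortTables <- function() {
  list(
    grooveA = toyClassTable("grooveA", c(6, -5, -3, 6, -1, -7, 6, 6, 1, -9)),
    grooveB = toyClassTable("grooveB", c(9, 5, -6, 3, -6, -6, -6, 7, 1, -4)),
    spread  = toyClassTable("spread",  c(1, 2, 10, 5, 8, 6, 3, 9, 4, 7)))
}

cohortCompendium <- function() PropertyCompendium(unname(cohortTables()))

cohortSpec <- function() {
  fixtureSpec(nTfs = 5, sitesPerTf = 30, siteLength = 10, icPerPosition = 0.10,
              constrainedPairs = data.frame(tf = c(1, 2),
                                            property = c("grooveA", "grooveB"),
                                            strength = c(0.8, 0.8),
                                            stringsAsFactors = FALSE),
              tfComposition = list(`1` = c(A = .33, C = .17, G = .17, T = .33),
                                   `2` = c(A = .17, C = .33, G = .33, T = .17)),
              genomeLength = 80000)
}

## run one full landscape on a fresh cohort; returns flagged "TF x property"
runCohortOnce <- function(comp = cohortCompendium(), nPerm = 200) {
  fx <- genFixtureGenome(cohortSpec(), comp)
  d <- tempfile()
  writeFixture(fx, d)
  g <- readGenome(file.path(d, "genome.fa"))
  sets <- readSiteTable(file.path(d, "sites.tsv"), genome = g)
  res <- buildLandscape(sets, comp, g, nPerm = nPerm, alpha = 0.05)
  unlink(d, recursive = TRUE)
  hits <- which(res$matrix, arr.ind = TRUE)
  sort(paste(rownames(res$matrix)[hits[, 1]], colnames(res$matrix)[hits[, 2]],
             sep = "x"))
}

## ---- naive oracles ----

naiveProfile <- function(seq, table) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  k <- propertyK(table)
  vals <- propertyValues(table)
  if (!isPositional(table)) {
    out <- rep(NA_real_, L - k + 1)
    for (i in seq_len(L - k + 1)) {
      w <- paste(s[i:(i + k - 1)], collapse = "")
      if (grepl("^[ACGT]+$", w)) out[i] <- vals[w]
    }
    out
  } else {
    acc <- rep(0, L); cnt <- rep(0L, L)
    for (i in seq_len(L - 2)) {
      w <- paste(s[i:(i + 2)], collapse = "")
      if (grepl("^[ACGT]+$", w)) {
        for (j in 0:2) {
          acc[i + j] <- acc[i + j] + vals[w, j + 1]
          cnt[i + j] <- cnt[i + j] + 1L
        }
      }
    }
    out <- acc / cnt
    out[cnt == 0] <- NA_real_
    out
  }
}

## all-pairs, all-positions double loop
naiveConservation <- function(seqs, table) {
  profs <- lapply(seqs, naiveProfile, table = table)
  n <- length(profs)
  P <- length(profs[[1]])
  pairMeans <- c()
  posSum <- rep(0, P); posCnt <- rep(0L, P)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- abs(profs[[i]] - profs[[j]])
    if (any(!is.na(d))) {
      pairMeans <- c(pairMeans, mean(d, na.rm = TRUE))
      ok <- !is.na(d)
      posSum[ok] <- posSum[ok] + d[ok]
      posCnt[ok] <- posCnt[ok] + 1L
    }
  }
  perPos <- posSum / posCnt
  perPos[posCnt == 0] <- NA_real_
  list(value = mean(pairMeans), perPosition = perPos)
}
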