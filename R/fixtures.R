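## Synthetic fixture generators: PWMs of prescribed information content,
## structurally constrained site sets with known ground truth, and toy
## genomes with embedded sites. All generators use the current RNG state;
## call set.seed() for reproducibility.

#' Generate a PWM with a target information content
#'
#' Mixes a (random or given) consensus with uniform base frequencies,
#' bisecting the mixture weight until the total information content is
#' within 0.1 bit of `targetIC`.
#'
#' @param length motif length
#' @param targetIC target information content in bits, in `[0, 2*length]`
#' @param consensus optional consensus sequence (length `length`); random
#'   if `NULL`
#' @return a [SitePWM-class] (with `nSites = 0`, as it was not built from
#'   sites)
#' @export
genPWM <- function(length, targetIC, consensus = NULL) {
  if (targetIC < 0 || targetIC > 2 * length + 1e-9)
    stop("unattainable target IC: must be in [0, ", 2 * length, "]")
  if (is.null(consensus)) {
    cons <- sample.int(4L, length, replace = TRUE)
  } else {
    cons <- .seqCodes(consensus)
    if (length(cons) != length || anyNA(cons)) stop("invalid consensus sequence")
  }
  icOf <- function(w) {
    fmax <- w + (1 - w) / 4
    f0 <- (1 - w) / 4
    term <- function(f) ifelse(f > 0, f * log2(f), 0)
    length * (2 + term(fmax) + 3 * term(f0))
  }
  if (targetIC <= 0) {
    w <- 0
  } else if (targetIC >= 2 * length) {
    w <- 1
  } else {
    lo <- 0; hi <- 1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (icOf(mid) < targetIC) lo <- mid else hi <- mid
    }
    w <- (lo + hi) / 2
  }
  if (abs(icOf(w) - targetIC) > 0.1)
    stop("could not reach target IC within 0.1 bit")
  freqs <- matrix((1 - w) / 4, length, 4, dimnames = list(NULL, .BASES))
  for (i in seq_len(length)) freqs[i, cons[i]] <- freqs[i, cons[i]] + w
  counts <- matrix(0L, length, 4, dimnames = list(NULL, .BASES))
  new("SitePWM", counts = counts, freqs = freqs, nSites = 0L)
}

#' Generate a structurally constrained site set
#'
#' Draws a candidate pool of `ceiling(n * (1 + 50 * strength))` sites from
#' the PWM, then greedily selects the `n` candidates minimizing the total
#' pairwise conservation-rate contribution under `table` (seeded at the
#' pool medoid; ties broken by candidate index). `strength = 0` reduces to
#' plain PWM sampling; higher strengths give site sets whose structural
#' conservation exceeds what their sequence conservation implies.
#'
#' @param pwm a [SitePWM-class]
#' @param n number of sites
#' @param table a [PropertyTable-class] (ignored at `strength = 0`)
#' @param strength constraint strength in `[0, 1]`
#' @param tfName name for the generated set
#' @return a [SiteSet-class]
#' @export
genConstrainedSiteSet <- function(pwm, n, table = NULL, strength = 0,
                                  tfName = "synthetic") {
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  m <- ceiling(n * (1 + 50 * strength))
  codes <- .samplePWMCodes(pwm, m)
  if (strength == 0 || is.null(table) || m == n) {
    sel <- seq_len(n)
  } else {
    X <- .profileMatrix(codes, table)
    D <- as.matrix(stats::dist(X, method = "manhattan")) / ncol(X)
    sel <- integer(n)
    ## seed at the densest n-neighborhood: the candidate whose n-1 nearest
    ## neighbors are closest in total (which.min takes lowest index on ties)
    knnCost <- apply(D, 1, function(r) sum(sort(r, partial = n)[seq_len(n)]))
    sel[1] <- which.min(knnCost)
    inSel <- rep(FALSE, m)
    inSel[sel[1]] <- TRUE
    acc <- D[, sel[1]]
    for (t in 2:n) {
      acc[inSel] <- Inf
      sel[t] <- which.min(acc)
      inSel[sel[t]] <- TRUE
      acc <- acc + D[, sel[t]]
    }
    sel <- sort(sel)
  }
  seqs <- apply(codes[sel, , drop = FALSE], 1, .codesToSeq)
  SiteSet(tfName, seqs)
}

#' Generate a site set constrained at designated positions
#'
#' PWM-samples `n` sites, then replaces the subsequence starting at
#' `at` (1-based) of every site with a word drawn uniformly from
#' `synonyms` -- sequence-diverse words chosen to have identical profile
#' values under the property of interest. Used to plant positionally
#' localized structural conservation.
#'
#' @param pwm a [SitePWM-class]
#' @param n number of sites
#' @param synonyms character vector of equal-length words
#' @param at 1-based start position of the substituted word
#' @param tfName name for the generated set
#' @return a [SiteSet-class]
#' @export
genPositionalConstrainedSiteSet <- function(pwm, n, synonyms, at,
                                            tfName = "synthetic") {
  L <- nrow(pwm@freqs)
  wlen <- unique(nchar(synonyms))
  if (length(wlen) != 1 || at < 1 || at + wlen - 1 > L)
    stop("synonyms must share one length and fit within the motif")
  codes <- .samplePWMCodes(pwm, n)
  pick <- synonyms[sample.int(length(synonyms), n, replace = TRUE)]
  for (i in seq_len(n)) codes[i, at:(at + wlen - 1)] <- .seqCodes(pick[i])
  SiteSet(tfName, apply(codes, 1, .codesToSeq))
}

#' Specification for a synthetic fixture cohort
#'
#' @param nTfs number of TFs
#' @param sitesPerTf sites per TF
#' @param siteLength site length in bp
#' @param icPerPosition per-position PWM information content in bits
#'   (default 0.5 -- diverse sites, as in permissive motif cohorts)
#' @param constrainedPairs data.frame with columns `tf` (index),
#'   `property`, `strength`, `consensus` (optional) naming the planted
#'   TF-property constraints
#' @param genomeLength toy genome length in bp
#' @param flankComposition base frequencies of the background genome
#' @param tfComposition optional named list (names = TF indices as
#'   character) of base-frequency vectors; listed TFs get a
#'   composition-biased PWM (every position drawn from that composition,
#'   emulating base-composition-biased motifs) instead of a
#'   consensus-mixture PWM
#' @param flankBp flank margin the placement must respect (sites are placed
#'   with at least `2 * flankBp` clearance)
#' @return a `FixtureSpec` list
#' @export
fixtureSpec <- function(nTfs = 5, sitesPerTf = 20, siteLength = 10,
                        icPerPosition = 0.5,
                        constrainedPairs = data.frame(tf = integer(),
                                                      property = character(),
                                                      strength = numeric()),
                        genomeLength = 50000,
                        flankComposition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        tfComposition = list(),
                        flankBp = 30) {
  structure(list(nTfs = nTfs, sitesPerTf = sitesPerTf, siteLength = siteLength,
                 icPerPosition = icPerPosition, constrainedPairs = constrainedPairs,
                 genomeLength = genomeLength, flankComposition = flankComposition,
                 tfComposition = tfComposition, flankBp = flankBp),
            class = "FixtureSpec")
}

#' Generate a toy genome with embedded binding sites
#'
#' Builds a background chromosome from `flankComposition`, generates one
#' site set per TF (constrained where `constrainedPairs` says so, plain
#' PWM samples otherwise), and embeds the sites at non-overlapping
#' positions with at least `2 * flankBp` clearance; roughly half the sites
#' are embedded on the minus strand. A gene is placed downstream of each
#' site so that the site falls in its promoter.
#'
#' @param spec a [fixtureSpec()] list
#' @param compendium a [PropertyCompendium-class] resolving the property
#'   names in `constrainedPairs`
#' @return list with `genome` ([Biostrings::DNAStringSet]), `sites`
#'   (data.frame in the [readSiteTable()] dialect), `genes` (data.frame),
#'   `siteSets` (the ground-truth list of [SiteSet-class]), `pwms`
#' @export
genFixtureGenome <- function(spec, compendium = NULL) {
  nSitesTotal <- spec$nTfs * spec$sitesPerTf
  margin <- 2L * spec$flankBp
  geneGap <- 60L; geneLen <- 120L
  slot <- spec$siteLength + 2L * margin + geneGap + geneLen
  if (nSitesTotal * slot > spec$genomeLength)
    stop("placement infeasible: need at least ", nSitesTotal * slot,
         " bp, genome is ", spec$genomeLength)
  ## ground-truth site sets
  cp <- spec$constrainedPairs
  pwms <- list(); siteSets <- list()
  for (t in seq_len(spec$nTfs)) {
    row <- if (nrow(cp)) which(cp$tf == t) else integer()
    consensus <- if (length(row) && "consensus" %in% names(cp) &&
                     nzchar(cp$consensus[row[1]])) cp$consensus[row[1]] else NULL
    comp <- spec$tfComposition[[as.character(t)]]
    if (!is.null(comp)) {
      freqs <- matrix(rep(comp[.BASES] / sum(comp), each = spec$siteLength),
                      spec$siteLength, 4, dimnames = list(NULL, .BASES))
      pwm <- new("SitePWM", counts = matrix(0L, spec$siteLength, 4,
                                            dimnames = list(NULL, .BASES)),
                 freqs = freqs, nSites = 0L)
    } else {
      pwm <- genPWM(spec$siteLength, spec$icPerPosition * spec$siteLength, consensus)
    }
    nm <- paste0("TF", t)
    if (length(row)) {
      tb <- compendium[[cp$property[row[1]]]]
      set <- genConstrainedSiteSet(pwm, spec$sitesPerTf, tb,
                                   cp$strength[row[1]], tfName = nm)
    } else {
      set <- genConstrainedSiteSet(pwm, spec$sitesPerTf, strength = 0, tfName = nm)
    }
    pwms[[nm]] <- pwm
    siteSets[[nm]] <- set
  }
  ## background chromosome
  bg <- sample(.BASES, spec$genomeLength, replace = TRUE,
               prob = spec$flankComposition[.BASES])
  ## non-overlapping placements: one slot per site, shuffled over TFs
  ord <- sample(nSitesTotal)
  siteRows <- vector("list", nSitesTotal)
  geneRows <- vector("list", nSitesTotal)
  allSites <- do.call(rbind, lapply(names(siteSets), function(nm)
    data.frame(tf = nm, seq = as.character(siteSets[[nm]]@sites),
               stringsAsFactors = FALSE)))
  starts <- integer(nSitesTotal)
  for (i in seq_len(nSitesTotal)) {
    s0 <- (i - 1L) * slot + margin            # 0-based site start within slot
    starts[ord[i]] <- s0
  }
  strands <- sample(c("+", "-"), nSitesTotal, replace = TRUE)
  for (i in seq_len(nSitesTotal)) {
    s0 <- starts[i]
    motif <- allSites$seq[i]
    embed <- if (strands[i] == "-") .revcompStr(motif) else motif
    bg[(s0 + 1):(s0 + spec$siteLength)] <- strsplit(embed, "")[[1]]
    siteRows[[i]] <- data.frame(tf = allSites$tf[i], chrom = "chr1",
                                start = s0, end = s0 + spec$siteLength,
                                strand = strands[i], sequence = motif,
                                stringsAsFactors = FALSE)
    g0 <- s0 + spec$siteLength + geneGap
    ## plus-strand gene downstream: its promoter (upstream region) covers the site
    geneRows[[i]] <- data.frame(gene_id = sprintf("gene%04d", i), chrom = "chr1",
                                start = g0, end = g0 + geneLen, strand = "+",
                                stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(paste(bg, collapse = ""))
  names(genome) <- "chr1"
  sites <- do.call(rbind, siteRows)
  sites <- sites[order(sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  list(genome = genome, sites = sites, genes = do.call(rbind, geneRows),
       siteSets = siteSets, pwms = pwms, spec = spec)
}

#' Write a generated fixture to disk
#'
#' @param fixture list from [genFixtureGenome()]
#' @param dir output directory
#' @return the directory, invisibly; writes `genome.fa`, `sites.tsv`,
#'   `genes.tsv`
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(fixture$genome, file.path(dir, "genome.fa"))
  utils::write.table(fixture$sites, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
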