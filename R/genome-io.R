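## Readers/writers for genomes, gene tables, TFBS tables and 8-mer affinity
## tables; site extraction and promoter mapping. All tabular interfaces use
## 0-based half-open (BED-style) coordinates; `oneBased = TRUE` converts
## 1-based closed inputs on the fly.

#' Read a genome FASTA
#'
#' @param path FASTA path (gzip supported)
#' @return a [Biostrings::DNAStringSet] named by chromosome
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0) stop("no sequences in FASTA: ", path)
  ## keep only the first whitespace-delimited token of each header
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicate chromosome names in ", path)
  g
}

#' Fetch a genomic slice
#'
#' @param genome a [Biostrings::DNAStringSet] as returned by [readGenome()]
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @param strand `"+"` or `"-"`; minus returns the reverse complement
#' @return character sequence of length `end - start`
#' @export
fetchSequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop("out-of-range fetch ", chrom, ":", start, "-", end, " (length ", len, ")")
  s <- Biostrings::subseq(genome[[chrom]], start + 1, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Read a TFBS coordinate table into per-TF site sets
#'
#' Dialect: tab-separated with header `tf, chrom, start, end, strand`
#' (0-based half-open) and an optional `sequence` column. When a genome is
#' supplied, site sequences are extracted from it (minus-strand sites
#' reverse-complemented into motif orientation) and any `sequence` column is
#' verified against the extraction. Per TF, only sites of the modal length
#' are kept and sites containing non-ACGT characters are dropped (both
#' logged via `message()`).
#'
#' @param path site table path
#' @param genome optional [Biostrings::DNAStringSet]; required when the
#'   table has no `sequence` column
#' @param oneBased set `TRUE` for 1-based closed input coordinates
#' @return named list of [SiteSet-class], one per TF
#' @export
readSiteTable <- function(path, genome = NULL, oneBased = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("tf", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (oneBased) df$start <- df$start - 1L
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  hasSeq <- "sequence" %in% names(df)
  if (is.null(genome) && !hasSeq)
    stop("need either a genome or a 'sequence' column to obtain site sequences")
  if (!is.null(genome)) {
    ext <- vapply(seq_len(nrow(df)), function(i)
      fetchSequence(genome, df$chrom[i], df$start[i], df$end[i], df$strand[i]),
      character(1))
    if (hasSeq) {
      bad <- which(toupper(df$sequence) != ext)
      if (length(bad))
        stop("row ", bad[1], ": sequence column does not match genome slice ",
             df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]])
    }
    df$sequence <- ext
  } else {
    df$sequence <- toupper(df$sequence)
  }
  out <- lapply(split(df, factor(df$tf, levels = unique(df$tf))), function(d) {
    len <- nchar(d$sequence)
    tabLen <- table(len)
    modal <- as.integer(names(tabLen)[which.max(tabLen)])
    if (any(len != modal)) {
      message("TF ", d$tf[1], ": dropping ", sum(len != modal),
              " site(s) not of modal length ", modal)
      d <- d[len == modal, , drop = FALSE]
    }
    clean <- grepl("^[ACGT]+$", d$sequence)
    if (!all(clean)) {
      message("TF ", d$tf[1], ": dropping ", sum(!clean), " site(s) with non-ACGT characters")
      d <- d[clean, , drop = FALSE]
    }
    if (nrow(d) == 0) return(NULL)
    coords <- GenomicRanges::GRanges(d$chrom,
                                     IRanges::IRanges(start = d$start + 1L, end = d$end),
                                     strand = d$strand)
    SiteSet(d$tf[1], d$sequence, coords = coords)
  })
  Filter(Negate(is.null), out)
}

#' Write site sets to the table dialect read by [readSiteTable()]
#'
#' @param sets list of [SiteSet-class] with coordinates
#' @param path output path
#' @export
writeSiteTable <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    if (is.null(s@coords)) stop("site set '", s@tfName, "' has no coordinates")
    data.frame(tf = s@tfName,
               chrom = as.character(GenomicRanges::seqnames(s@coords)),
               start = GenomicRanges::start(s@coords) - 1L,
               end = GenomicRanges::end(s@coords),
               strand = as.character(GenomicRanges::strand(s@coords)),
               sequence = as.character(s@sites),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep TFs with more than a minimum number of binding sites
#'
#' The landscape analysis restricts to TFs with *more than* `minSites`
#' sites (strict inequality; the default reproduces the more-than-15 rule).
#'
#' @param sets list of [SiteSet-class]
#' @param minSites strict lower bound on the site count
#' @return filtered list
#' @export
filterByMinSites <- function(sets, minSites = 15) {
  if (!.isWholeNumber(minSites) || minSites < 2) stop("minSites must be an integer >= 2")
  Filter(function(s) nSites(s) > minSites, sets)
}

#' Read a gene coordinate table
#'
#' Dialect: tab-separated with header `gene_id, chrom, start, end, strand`,
#' 0-based half-open.
#'
#' @inheritParams readSiteTable
#' @return a [GenomicRanges::GRanges] with a `gene_id` metadata column
#' @export
readGeneTable <- function(path, oneBased = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (oneBased) df$start <- df$start - 1L
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end),
                         strand = df$strand, gene_id = df$gene_id)
}

#' Map binding sites to genes via promoters
#'
#' The promoter is the `promoterBp` region upstream of the gene's
#' strand-aware start, truncated where it would overlap a neighboring gene
#' body (and at chromosome start). A site maps to a gene when it overlaps
#' that gene's promoter; a site overlapping several promoters (e.g. between
#' divergent genes) is assigned to the gene whose start is nearest to the
#' site midpoint, ties to the lower-coordinate gene.
#'
#' @param set a [SiteSet-class] with coordinates
#' @param genes a [GenomicRanges::GRanges] from [readGeneTable()]
#' @param promoterBp promoter length in bp upstream of the gene start
#'   (default 600)
#' @return data.frame with one row per site: `site`, `chrom`, `start`,
#'   `end`, `gene_id` (`NA` for unmapped sites)
#' @export
mapSitesToGenes <- function(set, genes, promoterBp = 600) {
  if (is.null(set@coords)) stop("site set has no coordinates")
  gdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                    start = GenomicRanges::start(genes) - 1L,
                    end = GenomicRanges::end(genes),
                    strand = as.character(GenomicRanges::strand(genes)),
                    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  ## promoter intervals, truncated at neighboring gene bodies
  prom <- lapply(seq_len(nrow(gdf)), function(i) {
    g <- gdf[i, ]
    same <- gdf[gdf$chrom == g$chrom & seq_len(nrow(gdf)) != i, , drop = FALSE]
    if (g$strand == "+") {
      lo <- max(0L, g$start - promoterBp)
      nb <- same$end[same$end <= g$start]
      if (length(nb)) lo <- max(lo, max(nb))
      c(lo, g$start)
    } else {
      hi <- g$end + promoterBp
      nb <- same$start[same$start >= g$end]
      if (length(nb)) hi <- min(hi, min(nb))
      c(g$end, hi)
    }
  })
  tss <- ifelse(gdf$strand == "+", gdf$start, gdf$end)
  sc <- set@coords
  schrom <- as.character(GenomicRanges::seqnames(sc))
  sstart <- GenomicRanges::start(sc) - 1L
  send <- GenomicRanges::end(sc)
  unknown <- setdiff(unique(schrom), unique(gdf$chrom))
  if (length(unknown)) stop("site on unknown chromosome: ", unknown[1])
  geneIds <- vapply(seq_along(sc), function(i) {
    mid <- (sstart[i] + send[i]) / 2
    hits <- which(vapply(seq_len(nrow(gdf)), function(j) {
      gdf$chrom[j] == schrom[i] && sstart[i] < prom[[j]][2] && send[i] > prom[[j]][1]
    }, logical(1)))
    if (!length(hits)) return(NA_character_)
    d <- abs(mid - tss[hits])
    best <- hits[d == min(d)]
    if (length(best) > 1) best <- best[which.min(gdf$start[best])]
    gdf$gene_id[best]
  }, character(1))
  data.frame(site = seq_along(sc), chrom = schrom, start = sstart, end = send,
             gene_id = geneIds, stringsAsFactors = FALSE)
}

#' Read an 8-mer binding-affinity table
#'
#' Tab-separated `kmer, score` (protein-binding-microarray scores); any
#' monotone affinity score is accepted.
#'
#' @param path affinity table path
#' @param tfName optional TF label attached as an attribute
#' @return named numeric vector of scores keyed by 8-mer
#' @export
readAffinityTable <- function(path, tfName = NULL) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  hasHeader <- length(first) >= 2 &&
    suppressWarnings(is.na(as.numeric(first[2])))
  df <- utils::read.table(path, sep = "\t", header = hasHeader,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("affinity table must have columns kmer, score")
  kmer <- toupper(df[[1]])
  score <- df[[2]]
  bad <- which(!grepl("^[ACGT]{8}$", kmer))
  if (length(bad))
    stop("row ", bad[1], ": '", df[[1]][bad[1]], "' is not an ACGT 8-mer")
  dup <- which(duplicated(kmer))
  if (length(dup)) stop("duplicate 8-mer: ", kmer[dup[1]])
  if (!is.numeric(score)) stop("affinity scores must be numeric")
  out <- stats::setNames(as.numeric(score), kmer)
  if (!is.null(tfName)) attr(out, "tfName") <- tfName
  out
}
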