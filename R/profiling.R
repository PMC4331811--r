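## Structural profiling: converting nucleotide sequences into numerical
## profiles and scalar levels under a property table.

#' Structural profile of a sequence
#'
#' Slides the property lookup along the sequence: the parametric value of
#' each k-nucleotide window is anchored at the window's *first* nucleotide,
#' so a k=2 table on a clean length-L sequence yields L-1 entries and a k=3
#' table L-2. For the positional (hydroxyl-radical cleavage) table every
#' nucleotide receives the intensities contributed by each trinucleotide
#' window covering it, averaged, giving L entries (terminal positions are
#' covered by fewer windows). Windows containing non-ACGT characters yield
#' `NA` entries.
#'
#' @param sequence a DNA string (character or [Biostrings::DNAString]);
#'   case-insensitive, DNA alphabet only
#' @param table a [PropertyTable-class]
#' @return numeric vector of profile values, `NA` at uninformative
#'   positions; attribute `anchor` records the window-anchoring convention
#' @export
structuralProfile <- function(sequence, table) {
  if (is(sequence, "XString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1)
    stop("sequence must be a single DNA string")
  codes <- .seqCodes(sequence)
  if (length(codes) < table@k)
    stop("sequence too short: length ", length(codes), " < k = ", table@k)
  p <- .profileMatrix(matrix(codes, nrow = 1), table)[1, ]
  attr(p, "anchor") <- "first-nucleotide"
  attr(p, "property") <- table@name
  p
}

#' Structural level of a sequence
#'
#' The mean of the non-missing entries of the structural profile: the
#' region-wide summary of one property for one sequence.
#'
#' @inheritParams structuralProfile
#' @return numeric scalar; attribute `nUsed` counts the entries averaged
#' @export
structuralLevel <- function(sequence, table) {
  p <- structuralProfile(sequence, table)
  ok <- !is.na(p)
  if (!any(ok)) stop("no informative positions in sequence under table '", table@name, "'")
  out <- mean(p[ok])
  attr(out, "nUsed") <- sum(ok)
  out
}

#' Enumerate all DNA k-mers
#'
#' @param k word length, 1 to 12
#' @return character vector of the 4^k k-mers in lexicographic order
#' @examples
#' length(enumerateKmers(8))  # 65536
#' @export
enumerateKmers <- function(k) {
  if (!.isWholeNumber(k) || k < 1 || k > 12) stop("k must be an integer in 1..12")
  .allKmers(k)
}
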