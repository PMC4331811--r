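#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement width consensusMatrix
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("GRangesOrNull", c("GRanges", "NULL"))

#' One DNA structural property table
#'
#' A nearest-neighbor parameterization of one DNA structural property: a
#' mapping from all di- or trinucleotides to parametric values (degrees,
#' angstroms, kcal/mol, ... depending on the property). Tables are
#' reverse-complement symmetric. The hydroxyl-radical cleavage table is
#' *positional*: each trinucleotide maps to a triple of per-nucleotide
#' intensities rather than a single value, and the triple of a word is the
#' reverse of the triple of its reverse complement.
#'
#' @slot name short property identifier
#' @slot k word length (2 or 3)
#' @slot category `"conformational"` or `"thermodynamic"`
#' @slot values numeric matrix with one row per k-mer (lexicographic
#'   rownames) and 1 column, or 3 columns for a positional table
#' @slot positional logical flag for the per-nucleotide-triple encoding
#' @export
setClass("PropertyTable",
  representation(name = "character", k = "integer", category = "character",
                 values = "matrix", positional = "logical"))

setValidity("PropertyTable", function(object) {
  msg <- character()
  if (length(object@name) != 1 || !nzchar(object@name)) msg <- c(msg, "name must be a single non-empty string")
  if (!(object@k %in% c(2L, 3L))) msg <- c(msg, "k must be 2 or 3")
  if (!(object@category %in% c("conformational", "thermodynamic")))
    msg <- c(msg, "category must be 'conformational' or 'thermodynamic'")
  expect <- .allKmers(object@k)
  if (nrow(object@values) != length(expect) || !identical(rownames(object@values), expect)) {
    missing <- setdiff(expect, rownames(object@values))
    if (length(missing))
      msg <- c(msg, sprintf("incomplete table '%s': missing k-mer %s", object@name, missing[1]))
    else msg <- c(msg, sprintf("table '%s': rows must be all %d-mers in lexicographic order", object@name, object@k))
  } else if (anyNA(object@values)) {
    msg <- c(msg, sprintf("table '%s' contains missing values", object@name))
  } else {
    nc <- ncol(object@values)
    if (object@positional && nc != 3L) msg <- c(msg, "positional table must have 3 value columns")
    if (!object@positional && nc != 1L) msg <- c(msg, "non-positional table must have 1 value column")
    rc <- .revcompStr(expect)
    if (!object@positional) {
      d <- abs(object@values[, 1] - object@values[rc, 1])
      if (any(d > 1e-9))
        msg <- c(msg, sprintf("symmetry violation in table '%s' at k-mer %s", object@name, expect[which.max(d)]))
    } else {
      d <- abs(object@values - object@values[rc, 3:1, drop = FALSE])
      if (any(d > 1e-9))
        msg <- c(msg, sprintf("symmetry violation in positional table '%s' at k-mer %s",
                              object@name, expect[which.max(apply(d, 1, max))]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' A compendium of structural property tables
#'
#' An ordered, uniquely named list of [PropertyTable-class] objects. The
#' shipped compendium ([structuralProperties()]) holds 35 tables.
#'
#' @export
setClass("PropertyCompendium", contains = "SimpleList",
         prototype = prototype(elementType = "PropertyTable"))

setValidity("PropertyCompendium", function(object) {
  if (length(object) == 0) return(TRUE)
  if (!all(vapply(object, is, logical(1), "PropertyTable")))
    return("all elements must be PropertyTable objects")
  nm <- vapply(object, function(t) t@name, character(1))
  if (is.null(names(object)) || !identical(unname(names(object)), unname(nm)))
    return("list names must equal table names")
  if (anyDuplicated(nm)) return("table names must be unique")
  TRUE
})

#' A set of aligned binding sites for one transcription factor
#'
#' Equal-length, motif-oriented binding-site sequences, optionally carrying
#' genomic coordinates (0-based half-open on input, stored as a [GRanges]).
#' Minus-strand sites are reverse-complemented at extraction time so that
#' profiles align positionally.
#'
#' @slot tfName transcription factor identifier
#' @slot sites a [Biostrings::DNAStringSet] of equal widths
#' @slot coords a [GenomicRanges::GRanges] parallel to `sites`, or `NULL`
#' @export
setClass("SiteSet",
  representation(tfName = "character", sites = "DNAStringSet", coords = "GRangesOrNull"))

setValidity("SiteSet", function(object) {
  msg <- character()
  if (length(object@tfName) != 1) msg <- c(msg, "tfName must be a single string")
  if (length(object@sites) < 1) msg <- c(msg, "at least one site required")
  w <- Biostrings::width(object@sites)
  if (length(w) && length(unique(w)) != 1) msg <- c(msg, "all sites must have the same length")
  if (!is.null(object@coords) && length(object@coords) != length(object@sites))
    msg <- c(msg, "coords must be parallel to sites")
  if (length(msg)) msg else TRUE
})

#' Position weight matrix of a site set
#'
#' Per-position base counts and frequencies of a [SiteSet-class], without
#' pseudocounts. Sequence conservation is summarized by the information
#' content, \eqn{\sum_{i} (2 + \sum_b f_{ib} \log_2 f_{ib})} bits.
#'
#' @slot counts integer matrix, length x 4 (columns A,C,G,T)
#' @slot freqs numeric matrix of base frequencies, rows summing to 1
#' @slot nSites number of sites the matrix was built from
#' @export
setClass("SitePWM",
  representation(counts = "matrix", freqs = "matrix", nSites = "integer"))

setValidity("SitePWM", function(object) {
  msg <- character()
  if (!identical(colnames(object@freqs), .BASES)) msg <- c(msg, "freqs columns must be A,C,G,T")
  if (!identical(dim(object@counts), dim(object@freqs))) msg <- c(msg, "counts/freqs dimension mismatch")
  if (any(abs(rowSums(object@freqs) - 1) > 1e-9)) msg <- c(msg, "freqs rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Pairwise structural conservation rate
#'
#' The mean absolute difference of structural profiles over all unordered
#' pairs of a TF's binding sites, normalized per informative profile
#' position. Low values mean high structural conservation.
#'
#' @slot value global rate (property units)
#' @slot nPairs number of site pairs averaged
#' @slot perPosition per-position rates (profile coordinates)
#' @slot property property name the rate was computed under
#' @export
setClass("ConservationRate",
  representation(value = "numeric", nPairs = "integer",
                 perPosition = "numeric", property = "character"))

setMethod("show", "PropertyTable", function(object) {
  cat(sprintf("PropertyTable '%s' (k=%d, %s%s)\n", object@name, object@k,
              object@category, if (object@positional) ", positional" else ""))
  v <- object@values
  cat(sprintf("  %d k-mers, value range [%.4g, %.4g]\n", nrow(v), min(v), max(v)))
})

setMethod("show", "PropertyCompendium", function(object) {
  k <- vapply(object, function(t) t@k, integer(1))
  cat(sprintf("PropertyCompendium with %d tables (%d dinucleotide, %d trinucleotide)\n",
              length(object), sum(k == 2), sum(k == 3)))
})

setMethod("show", "SiteSet", function(object) {
  cat(sprintf("SiteSet '%s': %d sites of length %d%s\n", object@tfName,
              length(object@sites), if (length(object@sites)) Biostrings::width(object@sites)[1] else 0L,
              if (is.null(object@coords)) "" else " (with genomic coordinates)"))
})

setMethod("show", "SitePWM", function(object) {
  cat(sprintf("SitePWM: length %d, %d sites, IC = %.3f bits\n",
              nrow(object@freqs), object@nSites, informationContent(object)))
})

setMethod("show", "ConservationRate", function(object) {
  cat(sprintf("ConservationRate [%s]: %.6g over %d pairs, %d positions\n",
              object@property, object@value, object@nPairs, length(object@perPosition)))
})

#' @describeIn PropertyTable-class construct a table from a named value
#'   vector (non-positional) or a k-mer x 3 matrix (positional)
#' @param name,category,values see slots
#' @export
PropertyTable <- function(name, values, category = "conformational") {
  if (is.matrix(values)) {
    positional <- ncol(values) == 3L
  } else {
    values <- matrix(values, ncol = 1, dimnames = list(names(values), NULL))
    positional <- FALSE
  }
  k <- as.integer(round(log(nrow(values), 4)))
  values <- values[order(rownames(values)), , drop = FALSE]
  new("PropertyTable", name = name, k = k, category = category,
      values = values, positional = positional)
}

#' @describeIn PropertyCompendium-class construct from a list of tables
#' @param tables list of [PropertyTable-class] objects
#' @export
PropertyCompendium <- function(tables) {
  names(tables) <- vapply(tables, function(t) t@name, character(1))
  new("PropertyCompendium", SimpleList(tables))
}

#' @describeIn SiteSet-class construct from sequences
#' @param tfName TF identifier
#' @param sites character vector or `DNAStringSet` of equal-length sequences
#' @param coords optional `GRanges` parallel to the sites
#' @export
SiteSet <- function(tfName, sites, coords = NULL) {
  if (!is(sites, "DNAStringSet")) sites <- Biostrings::DNAStringSet(toupper(sites))
  new("SiteSet", tfName = tfName, sites = sites, coords = coords)
}

#' Accessors for structcons classes
#'
#' Slot accessors for [SiteSet-class], [PropertyTable-class],
#' [SitePWM-class] and [ConservationRate-class] objects.
#' `propertyValues()` returns a named numeric vector for a non-positional
#' table and a k-mer x 3 matrix for the positional one.
#'
#' @param x the object
#' @name accessors
NULL

#' @rdname accessors
#' @export
tfName <- function(x) x@tfName
#' @rdname accessors
#' @export
siteSequences <- function(x) x@sites
#' @rdname accessors
#' @export
siteCoords <- function(x) x@coords
#' @rdname accessors
#' @export
nSites <- function(x) length(x@sites)
#' @rdname accessors
#' @export
siteLength <- function(x) if (length(x@sites)) Biostrings::width(x@sites)[1] else 0L
#' @rdname accessors
#' @export
propertyName <- function(x) x@name
#' @rdname accessors
#' @export
propertyCategory <- function(x) x@category
#' @rdname accessors
#' @export
propertyK <- function(x) x@k
#' @rdname accessors
#' @export
isPositional <- function(x) x@positional
#' @rdname accessors
#' @export
propertyValues <- function(x) {
  if (x@positional) x@values else stats::setNames(x@values[, 1], rownames(x@values))
}
#' @rdname accessors
#' @export
pwmFreqs <- function(x) x@freqs
#' @rdname accessors
#' @export
pwmCounts <- function(x) x@counts
#' @rdname accessors
#' @export
rateValue <- function(x) x@value
#' @rdname accessors
#' @export
ratePerPosition <- function(x) x@perPosition
#' @rdname accessors
#' @export
rateNPairs <- function(x) x@nPairs
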