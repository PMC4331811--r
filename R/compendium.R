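## Loading, validating, serializing and shuffling the structural property
## compendium. File dialect: tab-separated columns
##   property_name  category  kmer  value1 [value2 value3]
## with '#' comment lines; three value columns mark the positional
## (hydroxyl-radical cleavage) table.

#' Load a structural property compendium from file
#'
#' Reads a tab-separated property-table file and validates every table:
#' completeness (all 4^k k-mers present) and reverse-complement symmetry
#' (tolerance 1e-9). Tables with three value columns are stored as
#' positional (per-nucleotide triples).
#'
#' @param path path to the property-table file (gzip supported)
#' @return a [PropertyCompendium-class]
#' @seealso [structuralProperties()] for the shipped 35-table compendium
#' @export
readPropertyTables <- function(path) {
  if (!file.exists(path)) stop("property file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          fill = TRUE, stringsAsFactors = FALSE,
                          col.names = c("property_name", "category", "kmer",
                                        "value1", "value2", "value3"))
  if (nrow(df) == 0) stop("empty property file: ", path)
  tables <- lapply(split(df, factor(df$property_name, levels = unique(df$property_name))),
                   function(d) {
    positional <- any(!is.na(d$value3))
    if (anyDuplicated(d$kmer))
      stop("duplicate k-mer '", d$kmer[duplicated(d$kmer)][1], "' in table '",
           d$property_name[1], "'")
    k <- unique(nchar(d$kmer))
    if (length(k) != 1 || !(k %in% c(2, 3)))
      stop("table '", d$property_name[1], "': k-mers must all have length 2 or 3")
    expect <- .allKmers(k)
    missing <- setdiff(expect, d$kmer)
    if (length(missing))
      stop("incomplete table '", d$property_name[1], "': missing k-mer ", missing[1])
    if (positional) {
      v <- as.matrix(d[, c("value1", "value2", "value3")])
      rownames(v) <- d$kmer
    } else {
      v <- matrix(d$value1, ncol = 1, dimnames = list(d$kmer, NULL))
    }
    v <- v[expect, , drop = FALSE]
    new("PropertyTable", name = d$property_name[1], k = as.integer(k),
        category = d$category[1], values = v, positional = positional)
  })
  PropertyCompendium(unname(tables))
}

#' Write a compendium back to the file dialect read by [readPropertyTables()]
#'
#' @param compendium a [PropertyCompendium-class]
#' @param path output path
#' @export
writePropertyTables <- function(compendium, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tbl in as.list(compendium)) {
    v <- tbl@values
    vals <- apply(v, 1, function(r)
      paste(format(r, trim = TRUE, digits = 17, scientific = FALSE), collapse = "\t"))
    writeLines(paste(tbl@name, tbl@category, rownames(v), vals, sep = "\t"), con)
  }
  invisible(path)
}

.compendiumCache <- new.env(parent = emptyenv())

#' The shipped 35-property compendium
#'
#' Loads (and caches) the package's built-in compendium of 35 DNA
#' di-/trinucleotide structural property tables: 32 dinucleotide tables
#' (conformational geometry, groove parameters, stiffness/deformability,
#' and nearest-neighbor thermodynamics) and 3 trinucleotide tables
#' (DNase I bendability, nucleosome positioning preference, and the
#' positional hydroxyl-radical cleavage table). Thermodynamic tables carry
#' standard nearest-neighbor parameters; the remaining tables carry
#' representative values within published ranges (the file is labelled
#' synthetic accordingly).
#'
#' @return a [PropertyCompendium-class] with 35 tables
#' @export
structuralProperties <- function() {
  if (is.null(.compendiumCache$shipped)) {
    path <- system.file("extdata", "structural_properties_synthetic.tsv",
                        package = "structcons", mustWork = TRUE)
    .compendiumCache$shipped <- readPropertyTables(path)
  }
  .compendiumCache$shipped
}

#' Reverse-complement equivalence classes of k-mers
#'
#' Partitions all 4^k k-mers into classes \{w, revcomp(w)\}. For k = 2 there
#' are 10 classes (4 self-complementary dinucleotides), for k = 3 there are
#' 32 (no trinucleotide is self-complementary).
#'
#' @param k word length, 2 or 3
#' @return list of character vectors, named by the lexicographically
#'   smaller member
#' @export
rcClasses <- function(k) {
  if (!.isWholeNumber(k) || !(k %in% c(2, 3))) stop("k must be 2 or 3")
  w <- .allKmers(k)
  canon <- pmin(w, .revcompStr(w))
  split(w, factor(canon, levels = unique(canon)))
}

#' Shuffle a property table's values among k-mer classes
#'
#' Randomly permutes the parametric values among reverse-complement-collapsed
#' k-mer classes (10 dinucleotide or 32 trinucleotide classes), preserving
#' reverse-complement symmetry of the result. Used by the shuffled-table
#' null: scoring sites under shuffled tables asks whether conservation
#' depends on the property's true value assignment. Uses the current RNG
#' state; call `set.seed()` for reproducibility.
#'
#' @param table a non-positional [PropertyTable-class]
#' @return a new [PropertyTable-class] with permuted class values
#' @export
shuffleTable <- function(table) {
  if (table@positional)
    stop("unsupported shuffle: positional table '", table@name, "'")
  classes <- rcClasses(table@k)
  reps <- names(classes)
  vals <- table@values[reps, 1]
  perm <- vals[sample.int(length(vals))]
  v <- table@values
  for (i in seq_along(classes)) v[classes[[i]], 1] <- perm[i]
  methods::initialize(table, values = v)
}
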