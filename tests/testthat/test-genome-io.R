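writeFasta <- function(...) {
  f <- tempfile(fileext = ".fa")
  writeLines(c(...), f)
  f
}

test_that("genome fetch honors the 0-based half-open convention", {
  g <- readGenome(writeFasta(">chr1", "ACGT"))
  expect_identical(fetchSequence(g, "chr1", 0, 2), "AC")
  expect_identical(fetchSequence(g, "chr1", 0, 4, strand = "-"), "ACGT")
  expect_error(fetchSequence(g, "chr1", 0, 5), "out-of-range")
  expect_error(fetchSequence(g, "chr1", 2, 2), "out-of-range")
  expect_error(fetchSequence(g, "chrX", 0, 1), "unknown chromosome")
  expect_error(readGenome(writeFasta(">a", "AC", ">a", "GG")), "duplicate")
})

writeSites <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("site tables group per TF with motif orientation", {
  g <- readGenome(writeFasta(">chr1", "AACGTTTTACGGGG"))
  df <- data.frame(tf = "GCN4", chrom = "chr1",
                   start = c(0, 4, 8), end = c(3, 7, 11),
                   strand = c("+", "+", "-"))
  sets <- readSiteTable(writeSites(df), genome = g)
  expect_named(sets, "GCN4")
  expect_identical(as.character(siteSequences(sets$GCN4)),
                   c("AAC", "TTT", "CGT"))   # minus strand reverse-complemented
  expect_s4_class(siteCoords(sets$GCN4), "GRanges")

  ## a correct sequence column is accepted, a wrong one names the row
  df$sequence <- c("AAC", "TTT", "CGT")
  expect_silent(readSiteTable(writeSites(df), genome = g))
  df$sequence[2] <- "TTA"
  expect_error(readSiteTable(writeSites(df), genome = g), "row 2")
})

test_that("modal-length filtering and ambiguous-site dropping are logged", {
  df <- data.frame(tf = "X", chrom = "c", start = 0, end = 0, strand = "+",
                   sequence = c("AAAAAAA", "CCCCCCC", "GGGGGGG", "AAAAAAAAA"))
  expect_message(sets <- readSiteTable(writeSites(df)), "modal length")
  expect_identical(nSites(sets$X), 3L)
  expect_identical(siteLength(sets$X), 7L)

  df2 <- data.frame(tf = "Y", chrom = "c", start = 0, end = 0, strand = "+",
                    sequence = c("AANA", "CCCC", "GGGG"))
  expect_message(sets2 <- readSiteTable(writeSites(df2)), "non-ACGT")
  expect_identical(nSites(sets2$Y), 2L)
})

test_that("site-count filter is strictly greater-than", {
  mk <- function(n) SiteSet("t", replicate(n, randomSeq(6)))
  sets <- list(a = mk(16), b = mk(15), c = mk(40))
  kept <- filterByMinSites(sets, 15)
  expect_named(kept, c("a", "c"))
  expect_identical(filterByMinSites(list(), 15), list())
  expect_error(filterByMinSites(sets, 1), ">= 2")
})

test_that("promoter mapping truncates at neighbors and breaks ties low", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1001, 301), end = c(2000, 700)),
    strand = c("+", "+"), gene_id = c("gA", "gB"))
  site <- function(s, e) SiteSet("t", "AAAA",
    coords = GenomicRanges::GRanges("chr1", IRanges::IRanges(s + 1, e), strand = "+"))

  ## promoter of gA is [400,1000) until truncated by gB ending at 700
  m <- mapSitesToGenes(site(720, 724), genes)
  expect_identical(m$gene_id, "gA")
  m2 <- mapSitesToGenes(site(500, 504), genes)   # between gB's body and gA's truncated promoter
  expect_true(is.na(m2$gene_id))
  m3 <- mapSitesToGenes(site(100, 104), genes)   # in gB's promoter [0,300)
  expect_identical(m3$gene_id, "gB")
  m4 <- mapSitesToGenes(site(2500, 2504), genes) # outside every promoter
  expect_true(is.na(m4$gene_id))

  ## divergent pair, equidistant site -> lower-coordinate gene
  div <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 2001), end = c(1000, 3000)),
    strand = c("-", "+"), gene_id = c("left", "right"))
  mid <- mapSitesToGenes(site(1498, 1502), div)
  expect_identical(mid$gene_id, "left")

  expect_error(mapSitesToGenes(
    SiteSet("t", "AAAA", coords = GenomicRanges::GRanges("chrZ",
      IRanges::IRanges(1, 4))), genes), "unknown chromosome")
})

test_that("affinity tables parse and validate 8-mers", {
  f <- tempfile()
  writeLines(c("AAAAAAAA\t0.31", "ACGTACGT\t-0.12"), f)
  aff <- readAffinityTable(f, tfName = "Dal80")
  expect_length(aff, 2)
  expect_equal(unname(aff["ACGTACGT"]), -0.12)
  expect_identical(attr(aff, "tfName"), "Dal80")

  writeLines(c("kmer\tscore", "AAAAAAAA\t1", "AAAAAAAA\t2"), f)
  expect_error(readAffinityTable(f), "duplicate 8-mer")
  writeLines(c("AAAA\t1"), f)
  expect_error(readAffinityTable(f), "not an ACGT 8-mer")
})

test_that("site tables round-trip through write and read", {
  g <- readGenome(writeFasta(">chr1", paste(rep("ACGTTGCA", 20), collapse = "")))
  df <- data.frame(tf = c("A", "A", "B"), chrom = "chr1",
                   start = c(0, 8, 16), end = c(6, 14, 22),
                   strand = c("+", "-", "+"))
  sets <- readSiteTable(writeSites(df), genome = g)
  f2 <- tempfile()
  writeSiteTable(sets, f2)
  back <- readSiteTable(f2, genome = g)
  expect_identical(lapply(back, function(s) as.character(siteSequences(s))),
                   lapply(sets, function(s) as.character(siteSequences(s))))
})
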