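test_that("one-sided Mann-Whitney matches exact enumeration", {
  ## all 20 arrangements of ranks: the fully separated case
  expect_equal(mannWhitneyU(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05)
  expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6), "less"), 0.05)
  expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6), "two.sided"), 0.1)
})

test_that("flank comparison detects sites embedded above background", {
  ## toy table: AA-class value 10, everything else 0; genome of Cs with
  ## embedded A-runs -> site |level| 10, flank |level| 0
  tb <- toyClassTable("aa", c(10, rep(0, 9)))
  bg <- strrep("C", 500)
  sites <- data.frame(start = c(100, 200, 300, 400))
  seqchars <- strsplit(bg, "")[[1]]
  for (s in sites$start) seqchars[(s + 1):(s + 6)] <- "A"
  g <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
  names(g) <- "chr1"
  set <- SiteSet("t", rep("AAAAAA", 4),
                 coords = GenomicRanges::GRanges("chr1",
                   IRanges::IRanges(sites$start + 1, sites$start + 6), strand = "+"))
  res <- flankComparisonTest(set, tb, g, flankBp = 30)
  expect_equal(res$siteLevels, rep(10, 4))
  expect_equal(res$flankLevels, rep(0, 4))
  expect_lt(res$pValue, 0.05)

  ## same-background sites are not called
  set2 <- SiteSet("t", rep("CCCCCC", 4),
                  coords = GenomicRanges::GRanges("chr1",
                    IRanges::IRanges(c(41, 141, 241, 341), width = 6), strand = "+"))
  expect_gt(flankComparisonTest(set2, tb, g, flankBp = 30)$pValue, 0.5)

  expect_error(flankComparisonTest(SiteSet("n", rep("AAAAAA", 3)), tb, g),
               "lack genomic coordinates")
})

test_that("three permutations cannot reach corrected significance", {
  comp <- cohortCompendium()
  set.seed(1)
  sets <- list(TF1 = sampleSiteSet(genPWM(8, 4), 20, "TF1"))
  land <- runFilter1(sets, comp, nPerm = 3, alpha = 0.05)
  expect_identical(nrow(land), 3L)
  expect_false(any(land$passed1))   # min p = 1/4, times 3 properties > 0.05
})

test_that("positional-table pairs are skip-flagged in filter 2", {
  comp <- PropertyCompendium(list(structuralProperties()[["hydroxyl_radical_cleavage"]]))
  set.seed(2)
  sets <- list(TF1 = sampleSiteSet(genPWM(8, 2), 10, "TF1"))
  land <- runFilter1(sets, comp, nPerm = 20, alpha = 0.05)
  land$passed1 <- TRUE   # force a surviving positional pair
  expect_message(land2 <- runFilter2(land, sets, comp, nPerm = 20, alpha = 0.05),
                 "shuffle unsupported")
  expect_true(land2$shuffleSkipped[1])
  expect_false(land2$passed2[1])
  expect_true(is.na(land2$pShuffleNull[1]))
})

test_that("landscape filters are monotone and the output has full cardinality", {
  comp <- cohortCompendium()
  set.seed(3)
  fx <- genFixtureGenome(cohortSpec(), comp)
  d <- tempfile(); writeFixture(fx, d)
  g <- readGenome(file.path(d, "genome.fa"))
  sets <- readSiteTable(file.path(d, "sites.tsv"), genome = g)
  res <- buildLandscape(sets, comp, g, nPerm = 100, alpha = 0.05)
  l <- res$landscape
  expect_identical(nrow(l), 15L)          # 5 TFs x 3 properties
  expect_true(all(l$passed2 <= l$passed1))
  expect_true(all(l$passed3 <= l$passed2))
  expect_true(all(l$pPwmNull > 0 & l$pPwmNull <= 1))
  ## matrix mirrors the passed3 flags
  expect_identical(sum(res$matrix), sum(l$passed3))
  ## positional results only for full survivors, 1-based positions in range
  if (nrow(res$positional)) {
    expect_true(all(res$positional$position >= 1 & res$positional$position <= 9))
    key <- unique(paste(res$positional$tf, res$positional$property))
    expect_setequal(key, paste(l$tf, l$property)[l$passed3])
  }
  unlink(d, recursive = TRUE)
})

test_that("a fixed seed makes the whole landscape byte-identical", {
  comp <- cohortCompendium()
  run <- function(dir) {
    set.seed(11)
    spec <- cohortSpec()
    fx <- genFixtureGenome(spec, comp)
    d <- tempfile(); writeFixture(fx, d)
    g <- readGenome(file.path(d, "genome.fa"))
    sets <- readSiteTable(file.path(d, "sites.tsv"), genome = g)
    res <- buildLandscape(sets, comp, g, nPerm = 50, alpha = 0.05, seed = 99)
    writeLandscape(res, dir)
    unlink(d, recursive = TRUE)
  }
  d1 <- tempfile(); d2 <- tempfile()
  run(d1); run(d2)
  for (f in c("landscape.tsv", "matrix.tsv", "positional.tsv", "run.log"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("identical sites give uninformative positional p-values", {
  tb <- toyClassTable("t", 1:10)
  set <- SiteSet("same", rep("AAAAAA", 10))   # degenerate PWM
  pa <- positionalAnalysis(set, tb, nPerm = 50, alpha = 0.05)
  expect_equal(pa$pValues, rep(1, 5))
  expect_length(pa$significant, 0)
})
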