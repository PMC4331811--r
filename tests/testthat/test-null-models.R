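test_that("PWM counts, frequencies and information content are exact", {
  pwm <- buildPWM(SiteSet("a", c("AA", "AA")))
  expect_equal(unname(pwmFreqs(pwm)), rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)))
  expect_equal(informationContent(pwm), 4)

  pwm2 <- buildPWM(SiteSet("b", c("AC", "AG")))
  expect_equal(unname(pwmFreqs(pwm2)[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(pwmFreqs(pwm2)[2, ]), c(0, 0.5, 0.5, 0))
  expect_equal(informationContent(pwm2), 3)

  set.seed(1)
  pwm3 <- buildPWM(SiteSet("c", replicate(20, randomSeq(8))))
  expect_equal(unname(rowSums(pwmFreqs(pwm3))), rep(1, 8))
  expect_error(buildPWM(SiteSet("n", "ANA")), "non-ACGT")
})

test_that("PWM sampling reproduces the row frequencies", {
  ## degenerate PWM -> identical sites
  pwm <- buildPWM(SiteSet("a", c("AAA", "AAA")))
  set.seed(2)
  s <- sampleSiteSet(pwm, 5)
  expect_identical(as.character(siteSequences(s)), rep("AAA", 5))

  ## law of large numbers on a half-half row
  pwm2 <- buildPWM(SiteSet("b", c("AC", "CC")))  # position 1: A 0.5, C 0.5
  set.seed(3)
  draws <- sampleSiteSet(pwm2, 10000)
  fA <- mean(substr(as.character(siteSequences(draws)), 1, 1) == "A")
  expect_lt(abs(fA - 0.5), 3 * sqrt(0.25 / 10000))

  ## determinism under a fixed seed
  set.seed(4); x <- as.character(siteSequences(sampleSiteSet(pwm2, 10)))
  set.seed(4); y <- as.character(siteSequences(sampleSiteSet(pwm2, 10)))
  expect_identical(x, y)
})

test_that("empirical p-values follow the add-one convention", {
  expect_equal(empiricalPValue(0.5, c(0.4, 0.6, 0.7), "lower"), 0.5)
  expect_equal(empiricalPValue(0.1, rep(1, 99), "lower"), 1 / 100)
  expect_equal(empiricalPValue(0.5, rep(0.5, 10), "lower"), 1)   # ties are extreme
  expect_equal(empiricalPValue(2, c(1, 3), "upper"), 2 / 3)
  expect_error(empiricalPValue(1, numeric(0)), "empty null")

  ## monotone nonincreasing in the statistic (lower tail), never zero
  nulls <- rnorm(50)
  ps <- vapply(sort(rnorm(20)), empiricalPValue, numeric(1),
               nullStats = nulls, tail = "lower")
  expect_true(all(diff(ps) >= 0))
  expect_true(all(ps >= 1 / 51))
})

test_that("Bonferroni correction caps at one", {
  expect_equal(bonferroniCorrect(0.001, 35), 0.035)
  expect_equal(bonferroniCorrect(0.5, 35), 1)
  expect_equal(bonferroniCorrect(0.2, 1), 0.2)
  expect_equal(bonferroniCorrect(c(0.001, 0.5), 35), c(0.035, 1))
  expect_error(bonferroniCorrect(0.1, 0), "positive integer")
})

test_that("degenerate inputs give p = 1 in both null tests", {
  tb <- toyClassTable("t", 1:10)
  ident <- SiteSet("same", rep("AAAA", 5))   # degenerate PWM, rate 0
  res <- pwmNullTest(ident, tb, nPerm = 50)
  expect_equal(res$realStat, 0)
  expect_equal(res$pValue, 1)

  const <- toyClassTable("c", rep(2, 10))    # shuffling a constant table
  set.seed(5)
  set <- SiteSet("s", replicate(6, randomSeq(8)))
  res2 <- shuffledTableNullTest(set, const, nPerm = 50)
  expect_equal(res2$pValue, 1)
})

test_that("null tests are reproducible under a fixed seed", {
  tb <- toyClassTable("t", 1:10)
  set.seed(6)
  set <- SiteSet("s", replicate(8, randomSeq(10)))
  set.seed(7); a <- pwmNullTest(set, tb, 100)
  set.seed(7); b <- pwmNullTest(set, tb, 100)
  expect_identical(a, b)
  set.seed(8); c <- shuffledTableNullTest(set, tb, 100)
  set.seed(8); d <- shuffledTableNullTest(set, tb, 100)
  expect_identical(c, d)

  hr <- structuralProperties()[["hydroxyl_radical_cleavage"]]
  expect_error(shuffledTableNullTest(set, hr, 10), "unsupported shuffle")
})

test_that("structurally constrained sets are detected by both nulls", {
  tb <- cohortTables()$grooveA
  set.seed(9)
  freqs <- matrix(rep(c(A = .33, C = .17, G = .17, T = .33), each = 10), 10, 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- new("SitePWM", counts = matrix(0L, 10, 4,
                                        dimnames = list(NULL, c("A", "C", "G", "T"))),
             freqs = freqs, nSites = 0L)
  hits1 <- hits2 <- 0
  for (r in 1:10) {
    set <- genConstrainedSiteSet(pwm, 30, tb, strength = 0.8)
    hits1 <- hits1 + (pwmNullTest(set, tb, 100)$pValue <= 0.05)
    hits2 <- hits2 + (shuffledTableNullTest(set, tb, 100)$pValue <= 0.05)
  }
  expect_gte(hits1, 9)
  expect_gte(hits2, 9)
})
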