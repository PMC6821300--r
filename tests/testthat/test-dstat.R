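# Both D estimators, the delete-one jackknife, z tests, the windowed scan
# and the quartet suite.

test_that("pattern counting tallies a block correctly", {
  cnt <- countPatterns(c("ABBA", "BABA", "ABBA"), "b1")
  expect_equal(cnt$c_abba, 2L)
  expect_equal(cnt$c_baba, 1L)
  expect_equal(cnt$c_bbaa, 0L)
  expect_equal(cnt$n_sites, 3L)
  empty <- countPatterns(character(0))
  expect_equal(unlist(empty[, 2:5]), c(c_abba = 0L, c_baba = 0L,
                                       c_bbaa = 0L, n_sites = 0L))
})

test_that("count-form D is a ratio of sums, not a mean of ratios", {
  expect_equal(dFromCounts(data.frame(c_abba = 30, c_baba = 10))$d, 0.5)
  expect_equal(dFromCounts(data.frame(c_abba = 10, c_baba = 10))$d, 0)
  b <- data.frame(c_abba = c(2, 0, 2), c_baba = c(0, 2, 0))
  expect_equal(dFromCounts(b)$d, 1 / 3, tolerance = 1e-12)
  # asymmetric case: per-block D values are {1, -1} with mean 0, but the
  # pooled ratio of sums is (3 - 1) / 4 = 0.5
  asym <- data.frame(c_abba = c(3, 0), c_baba = c(0, 1))
  perBlock <- (asym$c_abba - asym$c_baba) / (asym$c_abba + asym$c_baba)
  expect_equal(mean(perBlock), 0)
  expect_equal(dFromCounts(asym)$d, 0.5)
  zero <- dFromCounts(data.frame(c_abba = 0, c_baba = 0))
  expect_true(is.na(zero$d))
  expect_equal(zero$flags, "undefined")
})

test_that("frequency-form D matches hand evaluation and bounds", {
  expect_equal(dFromFrequencies(rbind(c(0, 1, 1, 0)))$d, 1)
  r <- dFromFrequencies(rbind(c(0.2, 0.8, 1.0, 0.0)))
  expect_equal(r$abba, 0.64)
  expect_equal(r$baba, 0.04)
  expect_equal(r$d, 0.60 / 0.68, tolerance = 1e-12)
  expect_error(dFromFrequencies(rbind(c(1.2, 0, 0, 0))), "\\[0, 1\\]")
  expect_error(dFromFrequencies(rbind(c(0.5, 0.5, 0.5))), "4 columns")
})

test_that("with 0/1 frequencies the two estimators agree to machine precision", {
  set.seed(121)
  for (rep in 1:20) {
    derived <- matrix(rbinom(200, 1, 0.4), ncol = 4)
    eq2 <- dFromFrequencies(derived)
    pat <- classifyPattern(derived)
    eq1 <- dFromCounts(data.frame(c_abba = sum(pat == "ABBA"),
                                  c_baba = sum(pat == "BABA")))
    if (is.na(eq1$d)) expect_true(is.na(eq2$d))
    else expect_equal(eq2$d, eq1$d, tolerance = 1e-15)
  }
})

test_that("jackknife SE matches the hand example and a literal oracle", {
  b <- data.frame(c_abba = c(2, 0, 2), c_baba = c(0, 2, 0))
  jk <- jackknifeSE(b$c_abba - b$c_baba, b$c_abba + b$c_baba)
  expect_equal(sort(jk$thetas), c(0, 0, 1))
  expect_equal(jk$se, 2 / 3, tolerance = 1e-12)
  # identical blocks: zero variance
  same <- data.frame(c_abba = rep(3, 6), c_baba = rep(1, 6))
  expect_equal(jackknifeSE(same$c_abba - same$c_baba,
                           same$c_abba + same$c_baba)$se, 0)
  # random blocks against the literal delete-one recomputation
  set.seed(131)
  for (rep in 1:10) {
    rb <- data.frame(c_abba = rpois(30, 3), c_baba = rpois(30, 2))
    rb <- rb[rb$c_abba + rb$c_baba > 0, ]
    expect_equal(jackknifeSE(rb$c_abba - rb$c_baba,
                             rb$c_abba + rb$c_baba)$se,
                 oracleJackknife(rb), tolerance = 1e-12)
  }
  expect_error(jackknifeSE(1, 2), "insufficient_blocks")
})

test_that("z test reproduces the reported transcriptome-wide statistics", {
  # D = 0.0976 +/- 0.0110 and D = 0.1391 +/- 0.0109 are both significant at
  # p < 0.001 under the two-tailed normal test
  z1 <- 0.0976 / 0.0110
  expect_equal(z1, 8.873, tolerance = 1e-3)
  expect_lt(2 * (1 - pnorm(z1)), 0.001)
  z2 <- 0.1391 / 0.0109
  expect_equal(z2, 12.76, tolerance = 1e-3)
  expect_lt(2 * (1 - pnorm(z2)), 0.001)
  # and the DResult plumbing produces z = d / se with those semantics
  sim <- simulateLocusPatterns(simulationConfig(nLoci = 3000, gamma = 0.25,
                                                seed = 41))
  res <- dTest(sim$counts, c("P1", "P2", "P3", "O"))
  expect_equal(dZ(res), dValue(res) / dSE(res))
  expect_equal(dPValue(res), 2 * (1 - pnorm(abs(dZ(res)))))
  expect_true(abs(dValue(res)) <= 1)
})

test_that("D is antisymmetric under P1/P2 exchange in both modes", {
  sim <- simulateLocusPatterns(simulationConfig(nLoci = 500, gamma = 0.2,
                                                seed = 51))
  fwd <- dTest(sim$counts, c("P1", "P2", "P3", "O"))
  swapped <- data.frame(c_abba = sim$counts$c_baba,
                        c_baba = sim$counts$c_abba)
  rev <- dTest(swapped, c("P2", "P1", "P3", "O"))
  expect_equal(dValue(rev), -dValue(fwd), tolerance = 1e-15)
  expect_equal(abs(dZ(rev)), abs(dZ(fwd)), tolerance = 1e-12)
  set.seed(52)
  p <- matrix(runif(400), ncol = 4)
  expect_equal(dFromFrequencies(p[, c(2, 1, 3, 4)])$d,
               -dFromFrequencies(p)$d, tolerance = 1e-12)
})

test_that("degenerate SE cases are flagged", {
  one <- data.frame(c_abba = 3, c_baba = 1)
  res <- dTest(one, c("P1", "P2", "P3", "O"))
  expect_true(is.na(dSE(res)))
  expect_true("se_unavailable" %in% res@flags)
  same <- data.frame(c_abba = rep(3, 4), c_baba = rep(1, 4))
  deg <- dTest(same, c("P1", "P2", "P3", "O"))
  expect_equal(dPValue(deg), 0)
  expect_true("degenerate" %in% deg@flags)
})

test_that("windowed scan: per-window and chromosome-level estimates", {
  cfg <- simulationConfig(gamma = 0, seed = 61)
  sim <- simulateWindowFrequencies(cfg, nWindows = 300, snpsPerWindow = 100)
  wd <- windowedD(sim$snps, cfg@quartet, cfg@windowSize)
  expect_equal(nrow(wd$windows), 300L)
  # null: roughly nominal rejection at |z| > 1.96 (4 binomial SDs of slack
  # around 5%, plus jackknife approximation)
  fr <- mean(abs(wd$windows$z) > 1.96, na.rm = TRUE)
  expect_gt(fr, 0.01)
  expect_lt(fr, 0.10)
  # chromosome-level D near zero under the null
  chrom <- wd$chromosomes$chr1
  expect_lt(abs(dZ(chrom)), 3)
  expect_equal(nBlocks(chrom), 300L)
  # single window: chromosome D equals the window D, SE unavailable
  one <- sim$snps[sim$snps$pos < cfg@windowSize, ]
  wd1 <- windowedD(one, cfg@quartet, cfg@windowSize)
  expect_equal(dValue(wd1$chromosomes$chr1), wd1$windows$D[1])
  expect_true("se_unavailable" %in% wd1$chromosomes$chr1@flags)
  expect_error(windowedD(sim$snps, c("a", "b", "c", "d")), "absent")
})

test_that("quartet suite preserves order and recovers planted introgression", {
  cfg <- simulationConfig(nLoci = 40, gamma = 0.5, seed = 71)
  sim <- simulateClusterAlignments(cfg)
  quartets <- list(c("sara", "hortense", "erato", "iulia"),
                   c("hortense", "sara", "erato", "iulia"),
                   c("sara", "erato", "hortense", "iulia"))
  suite <- runDSuite(sim$alignments, quartets)
  expect_equal(nrow(suite), 3L)
  expect_equal(suite$P1, c("sara", "hortense", "sara"))
  # P1/P2 swap negates D exactly
  expect_equal(suite$D[2], -suite$D[1], tolerance = 1e-12)
  expect_equal(abs(suite$z[2]), abs(suite$z[1]), tolerance = 1e-9)
  expect_error(runDSuite(sim$alignments, list(c("sara", "x", "y", "iulia"))),
               "unknown label")
})

test_that("quartet concordance majority reflects the simulated class mix", {
  cfg <- simulationConfig(nLoci = 150, gamma = 0.3, mutRate = 0.05, seed = 81)
  sim <- simulateLocusPatterns(cfg)
  # concordance on pattern counts directly (majority = argmax, ties unresolved)
  counts <- sim$counts
  maj <- apply(counts[, c("c_bbaa", "c_abba", "c_baba")], 1, function(x) {
    top <- which(x == max(x))
    if (length(top) > 1) "unresolved" else c("BBAA", "ABBA", "BABA")[top]
  })
  p <- classProbabilities(0.3, log(2))
  expAbba <- p[["introgressed"]] + p[["ils_abba"]]
  obs <- mean(maj == "ABBA" & counts$n_sites > 0)
  expect_lt(abs(obs - expAbba * mean(counts$n_sites > 0)),
            4 * sqrt(expAbba * (1 - expAbba) / 150))
  # and the alignment-level API agrees on a small set
  simA <- simulateClusterAlignments(simulationConfig(nLoci = 8, seed = 82))
  qc <- quartetConcordance(simA$alignments, cfg@quartet)
  expect_equal(nrow(qc), 8L)
  expect_true(all(qc$majority %in% c("BBAA", "ABBA", "BABA", "unresolved")))
})
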