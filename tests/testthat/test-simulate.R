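# Generative model: closed-form expected D, hidden-class mixture, and the
# determinism contract of the seeded generators.

test_that("expectedD matches the closed form and its limits", {
  expect_equal(expectedD(0, 1), 0)
  expect_equal(expectedD(0, 0.37), 0)
  # t -> Inf: all discordance is introgression
  expect_equal(expectedD(0.3, 50), 1, tolerance = 1e-12)
  # hand evaluation: gamma = 0.1, t = ln 2 gives q = 1/6, g = 0.05
  expect_equal(expectedD(0.1, log(2)), 0.05 / (0.05 + 1 / 3))
  expect_error(expectedD(1.2, 1), "gamma")
  expect_error(expectedD(0.5, -1), "tInternal")
  # gamma = 0 and t = 0 leaves no informative sites: g + 2q stays positive
  # only through q, so only g = q = 0 is degenerate
  expect_error(expectedD(0, Inf), "informative")
})

test_that("expectedD is monotonically increasing in gamma", {
  for (t in c(0.2, log(2), 2)) {
    d <- expectedD(seq(0, 1, by = 0.05), t)
    expect_true(all(diff(d) > 0))
  }
})

test_that("class probabilities form a distribution matched by simulation", {
  p <- classProbabilities(0.3, log(2))
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  sim <- simulateLocusPatterns(simulationConfig(nLoci = 10000, gamma = 0.3,
                                                seed = 77))
  obs <- table(factor(sim$truth$class, levels = names(p))) / 10000
  for (cl in names(p)) {
    sd4 <- 4 * sqrt(p[[cl]] * (1 - p[[cl]]) / 10000)
    expect_lt(abs(obs[[cl]] - p[[cl]]), sd4 + 1e-12)
  }
})

test_that("locus patterns follow the class truth table and the null is symmetric", {
  sim <- simulateLocusPatterns(simulationConfig(nLoci = 2000, gamma = 0,
                                                seed = 3))
  pat <- c(introgressed = "ABBA", ils_abba = "ABBA", ils_baba = "BABA",
           ils_bbaa = "BBAA", concordant = "BBAA")
  col <- c(ABBA = "c_abba", BABA = "c_baba", BBAA = "c_bbaa")
  for (i in c(1, 500, 2000)) {
    expect_equal(sim$counts[[col[[pat[[sim$truth$class[i]]]]]]][i],
                 sim$truth$n_informative_sites[i])
  }
  # gamma = 0: ABBA and BABA totals equal within binomial noise, D near 0
  res <- dTest(sim$counts, c("P1", "P2", "P3", "O"))
  tot <- sum(sim$counts$c_abba) + sum(sim$counts$c_baba)
  expect_lt(abs(sum(sim$counts$c_abba) - sum(sim$counts$c_baba)),
            4 * sqrt(tot * 0.25))
  expect_lt(abs(dValue(res)), 3 * dSE(res))
})

test_that("fixed seed gives identical outputs; different seeds differ", {
  cfg <- simulationConfig(nLoci = 200, gamma = 0.15, seed = 11)
  expect_identical(simulateLocusPatterns(cfg), simulateLocusPatterns(cfg))
  cfgS <- simulationConfig(nLoci = 4, seed = 11)
  a1 <- simulateClusterAlignments(cfgS)
  a2 <- simulateClusterAlignments(cfgS)
  expect_identical(lapply(a1$alignments, as.character),
                   lapply(a2$alignments, as.character))
  w1 <- simulateWindowFrequencies(cfg, nWindows = 10)
  w2 <- simulateWindowFrequencies(cfg, nWindows = 10)
  expect_identical(w1, w2)
  cfg2 <- simulationConfig(nLoci = 200, gamma = 0.15, seed = 12)
  expect_false(identical(simulateLocusPatterns(cfg2)$counts,
                         simulateLocusPatterns(cfg)$counts))
})

test_that("pooled D on simulated patterns converges to the closed form", {
  cfg <- simulationConfig(nLoci = 5000, gamma = 0.2, seed = 19)
  sim <- simulateLocusPatterns(cfg)
  res <- dTest(sim$counts, c("P1", "P2", "P3", "O"))
  expect_lt(abs(dValue(res) - expectedD(0.2, log(2))), 3 * dSE(res))
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(gamma = 1.4), "gamma")
  expect_error(simulationConfig(tInternal = -0.1), "tInternal")
  expect_error(simulationConfig(sitesPerLocus = 100), "multiple of 3")
  expect_error(simulationConfig(taxa = letters[1:5]), "8 labels")
  expect_error(simulationConfig(quartet = c("x", "y", "z", "w")),
               "appear in 'taxa'")
})

test_that("mutRate = 0 gives identical sequences across all eight taxa", {
  sim <- simulateClusterAlignments(simulationConfig(nLoci = 2, mutRate = 0,
                                                    seed = 8),
                                   edgeLength = 0)
  for (aln in sim$alignments) {
    s <- as.character(aln)
    expect_equal(length(unique(s)), 1L)
    expect_equal(nrow(extractBiallelicSites(aln)), 0L)
  }
})

test_that("simulated alignments are gap-free, translatable and codon-complete", {
  sim <- simulateClusterAlignments(simulationConfig(nLoci = 3, seed = 13))
  for (aln in sim$alignments) {
    s <- as.character(aln)
    expect_true(all(nchar(s) == 900L))
    expect_false(any(grepl("-", s)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(s)))
    expect_false(any(grepl("\\*", aa)))
  }
})

test_that("window frequencies: haploid sampling reduces Eq. 2 to Eq. 1", {
  cfg <- simulationConfig(nChromPerPop = 1L, gamma = 0.3, seed = 23)
  sim <- simulateWindowFrequencies(cfg, nWindows = 8)
  expect_true(all(sim$snps$derived_freq %in% c(0, 1)))
  # Eq. 2 on 0/1 frequencies equals Eq. 1 on the same polarized sites
  wide <- matrix(sim$snps$derived_freq, ncol = 4, byrow = TRUE)
  eq2 <- dFromFrequencies(wide)
  derived <- wide
  pat <- classifyPattern(derived)
  eq1 <- dFromCounts(data.frame(c_abba = sum(pat == "ABBA"),
                                c_baba = sum(pat == "BABA")))
  expect_equal(eq2$d, eq1$d, tolerance = 1e-12)
})

test_that("introgressed tracts rank top in the windowed scan", {
  cfg <- simulationConfig(gamma = 0.9, seed = 29)
  sim <- simulateWindowFrequencies(cfg, nWindows = 50, tractFrac = 0.2,
                                   snpsPerWindow = 100)
  wd <- windowedD(sim$snps, cfg@quartet, cfg@windowSize)
  merged <- merge(wd$windows, sim$truth, by = c("chrom", "start"))
  expect_gt(mean(merged$D[merged$introgressed]),
            mean(merged$D[!merged$introgressed]))
  top <- merged$introgressed[order(-merged$D)][1:5]
  expect_true(all(top))
})
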