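# Isoform reduction, the k-mer similarity scorer, reciprocal best hits and
# eight-species clique clustering.

test_that("longest isoform is kept, ties broken lexicographically", {
  recs <- data.frame(
    species = c("s1", "s1", "s1", "s2", "s1", "s1"),
    gene_id = c("g1", "g1", "g2", "g1", "g3", "g3"),
    isoform_id = c("i1", "i2", "i1", "i1", "iso2", "iso10"),
    cds = c(strrep("A", 300), strrep("A", 450), "ATGATG",
            "ATG", strrep("C", 300), strrep("C", 300)),
    stringsAsFactors = FALSE
  )
  out <- selectLongestIsoform(recs)
  expect_equal(nrow(out), 4L)
  expect_equal(out$isoform_id[out$species == "s1" & out$gene_id == "g1"], "i2")
  # single-isoform gene unchanged
  expect_equal(out$cds[out$species == "s1" & out$gene_id == "g2"], "ATGATG")
  # equal lengths: "iso10" < "iso2" lexicographically
  expect_equal(out$isoform_id[out$gene_id == "g3"], "iso10")
  empty <- recs[0, ]
  expect_equal(nrow(selectLongestIsoform(empty)), 0L)
})

test_that("scorer: identity is maximal, short input flagged, noise rejected", {
  s <- randomDna(200)
  hit <- scorePair(s, s)
  expect_equal(hit$score, 200)
  expect_equal(hit$aligned_length, 200L)
  expect_equal(scorePair("ACGT", "ACGT")$flags, "too_short")
  expect_equal(scorePair("ACGT", "ACGT")$score, 0)
  # unrelated random 500-bp pairs pass the default threshold < 1% of the time
  set.seed(101)
  hits <- replicate(300, scorePair(randomDna(500), randomDna(500))$score >= 30)
  expect_lt(mean(hits), 0.01)
})

test_that("scorer retains a 5%-mutated copy above threshold", {
  set.seed(7)
  s <- randomDna(500)
  nt <- strsplit(s, "")[[1]]
  idx <- sample(500, 25)
  nt[idx] <- vapply(nt[idx],
                    function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    "")
  hit <- scorePair(s, paste(nt, collapse = ""))
  expect_gte(hit$score, 30)
  expect_gt(hit$aligned_length, 250L)
})

test_that("reciprocal best hits require mutual uniqueness", {
  set.seed(15)
  g1 <- randomDna(300); g2 <- randomDna(300)
  # identical single-gene sets: one pair
  expect_equal(nrow(reciprocalBestHits(c(a = g1), c(b = g1))), 1L)
  # a's best hit is b, but b's best hit is a2 (an exact copy beats a mutated
  # one): no pair for a
  mut <- function(s, n) {
    nt <- strsplit(s, "")[[1]]
    i <- sample(length(nt), n)
    nt[i] <- vapply(nt[i],
                    function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    "")
    paste(nt, collapse = "")
  }
  a <- mut(g1, 30)
  rbh <- reciprocalBestHits(c(a = a, a2 = g1), c(b = g1))
  expect_equal(rbh$id_a, "a2")
  expect_false("a" %in% rbh$id_a)
  # no qualifying pair: empty result
  expect_equal(nrow(reciprocalBestHits(c(a = g1), c(b = g2))), 0L)
})

test_that("best-hit ties resolve by aligned length then id, matching brute force", {
  set.seed(33)
  core <- randomDna(240)
  ext <- paste0(core, randomDna(120))
  # B holds an exact duplicate pair: same score against core, longer
  # alignment wins; identical duplicates then fall to lexicographic id
  setA <- c(a1 = ext)
  setB <- c(b_long = ext, b_short = core)
  rbh <- reciprocalBestHits(setA, setB)
  expect_equal(rbh$id_b, "b_long")
  setB2 <- c(b2 = core, b1 = core)
  rbh2 <- reciprocalBestHits(c(a1 = core), setB2)
  expect_equal(rbh2$id_b, "b1")
  # brute-force check of best-hit selection on a toy set
  setA3 <- c(x = core, y = mutSeq <- paste0(randomDna(100), core))
  best <- vapply(names(setA3), function(i) {
    sc <- vapply(names(setB2), function(j)
      scorePair(setA3[[i]], setB2[[j]])$score, 0)
    names(sc)[order(-sc, names(setB2))][1]
  }, "")
  rbh3 <- reciprocalBestHits(setA3, setB2)
  for (r in seq_len(nrow(rbh3)))
    expect_equal(rbh3$id_b[r], unname(best[rbh3$id_a[r]]))
})

test_that("clique clustering: identical sets give one cluster per gene", {
  set.seed(44)
  genes <- setNames(vapply(1:5, function(i) randomDna(300), ""),
                    paste0("g", 1:5))
  sets <- rep(list(genes), 8)
  names(sets) <- paste0("sp", 1:8)
  m <- buildClusters(sets)
  expect_equal(length(unique(m$cluster_id)), 5L)
  expect_equal(nrow(m), 40L)
  # every cluster holds the same gene id in all species
  coherent <- tapply(m$gene_id, m$cluster_id,
                     function(g) length(unique(g)) == 1)
  expect_true(all(coherent))
  # one species missing a gene: that cluster disappears
  sets2 <- sets
  sets2$sp8 <- sets2$sp8[-3]
  m2 <- buildClusters(sets2)
  expect_equal(length(unique(m2$cluster_id)), 4L)
  expect_false("g3" %in% m2$gene_id)
  # zero-sequence species is an error
  sets3 <- sets
  sets3$sp2 <- sets3$sp2[0]
  expect_error(buildClusters(sets3), "empty_species")
  expect_error(buildClusters(sets[1:4]), "8 species")
})

test_that("cluster membership is invariant under species input order", {
  cfg <- simulationConfig(nLoci = 6, seed = 61)
  sim <- simulateClusterAlignments(cfg)
  sets <- speciesSetsFromSim(sim, cfg@taxa)
  m1 <- buildClusters(sets)
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  m2 <- buildClusters(sets[perm])
  key <- function(m) sort(tapply(m$gene_id, m$cluster_id,
                                 function(g) paste(sort(g), collapse = "|")))
  expect_equal(unname(key(m1)), unname(key(m2)))
})

test_that("a cross-mapped paralog breaks the clique, matching exhaustive search", {
  set.seed(55)
  genes <- setNames(vapply(1:3, function(i) randomDna(300), ""),
                    paste0("g", 1:3))
  sets <- rep(list(genes), 8)
  names(sets) <- paste0("sp", 1:8)
  # sp5 lost g2 and kept a duplicate of g1 under g2's name: g2's clique
  # cannot close (sp5_g2 maps back to everyone's g1, already taken by the
  # g1 clique); exhaustive reasoning says exactly clusters {g1, g3} survive
  sets$sp5[["g2"]] <- genes[["g1"]]
  m <- buildClusters(sets)
  cl <- tapply(m$gene_id, m$cluster_id, function(g) unique(g))
  expect_equal(length(cl), 2L)
  expect_setequal(unlist(lapply(cl, unique)), c("g1", "g3"))
})

test_that("ortholog hit ratio caps at 1 and flags overhangs", {
  r <- orthologHitRatio(c(900, 450, 950), 900)
  expect_equal(r$ratio, c(1, 0.5, 1))
  expect_equal(r$capped, c(FALSE, FALSE, TRUE))
  expect_error(orthologHitRatio(100, 0), "positive")
})
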