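# Independent oracles used to check the package's NG86 and jackknife
# implementations. These deliberately use plain loops and their own
# bookkeeping rather than the package's precomputed tables.

oracleCode <- as.list(Biostrings::GENETIC_CODE)
oracleSense <- names(oracleCode)[unlist(oracleCode) != "*"]
oracleBases <- c("A", "C", "G", "T")

# brute-force synonymous site count of one codon: enumerate all 9 single-base
# mutations, drop those creating stops, take the synonymous fraction per
# position (position weight 1)
oracleSitesCodon <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  aa0 <- oracleCode[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; counted <- 0
    for (b in oracleBases) {
      if (b == nt[pos]) next
      alt <- nt
      alt[pos] <- b
      aa <- oracleCode[[paste(alt, collapse = "")]]
      if (aa == "*") next
      counted <- counted + 1
      if (aa == aa0) syn <- syn + 1
    }
    if (counted > 0) s <- s + syn / counted
  }
  s
}

# all permutations of a vector (k <= 3 here)
oraclePerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oraclePerms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# factorial path enumeration of (sd, nd) for one codon pair; NULL when every
# path passes through a stop codon
oracleSubsCodon <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  diffPos <- which(a != b)
  if (length(diffPos) == 0) return(c(sd = 0, nd = 0))
  sTot <- 0; nTot <- 0; nValid <- 0
  for (path in oraclePerms(diffPos)) {
    cur <- a; s <- 0; n <- 0; valid <- TRUE
    for (pos in path) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aaN <- oracleCode[[paste(nxt, collapse = "")]]
      if (aaN == "*") { valid <- FALSE; break }
      if (aaN == oracleCode[[paste(cur, collapse = "")]]) s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    if (valid) { sTot <- sTot + s; nTot <- nTot + n; nValid <- nValid + 1 }
  }
  if (nValid == 0) return(NULL)
  c(sd = sTot / nValid, nd = nTot / nValid)
}

# literal delete-one jackknife on the count-form D
oracleJackknife <- function(blocks) {
  n <- nrow(blocks)
  thetas <- vapply(seq_len(n), function(i) {
    b <- blocks[-i, , drop = FALSE]
    (sum(b$c_abba) - sum(b$c_baba)) / (sum(b$c_abba) + sum(b$c_baba))
  }, 0)
  sqrt(((n - 1) / n) * sum((thetas - mean(thetas))^2))
}

randomDna <- function(n) paste(sample(oracleBases, n, replace = TRUE),
                               collapse = "")

# per-species CDS sets derived from simulated cluster alignments, with
# species-prefixed gene ids (what a real per-species FASTA would hold)
speciesSetsFromSim <- function(sim, taxa) {
  sets <- lapply(taxa, function(sp) {
    s <- vapply(sim$alignments, function(a)
      as.character(a[[match(sp, names(a))]]), "")
    names(s) <- sprintf("%s_%s", sp, names(sim$alignments))
    s
  })
  names(sets) <- taxa
  sets
}
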