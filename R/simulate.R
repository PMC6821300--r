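## Synthetic-data generators: every downstream stage of the pipeline can be
## exercised on seeded data with known introgression proportion, hidden
## genealogy class and per-locus omega.

#' Closed-form expected D under the generative mixture
#'
#' Under the simulator's three-class gene-tree mixture, an informative site is
#' ABBA with probability \eqn{g + q}, BABA with probability \eqn{q}, where
#' \eqn{q = \exp(-t)/3} is the probability of each incomplete-lineage-sorting
#' resolution and \eqn{g = \gamma(1 - 3q)} is the introgression excess. The
#' expected Patterson's D is therefore
#' \deqn{E[D] = \frac{g}{g + 2q}.}
#'
#' @param gamma introgression proportion in `[0, 1]`.
#' @param tInternal internal branch length in coalescent units, `>= 0`.
#' @return the expected D value in `[0, 1]`.
#' @examples
#' expectedD(0, 1)                 # no introgression: D = 0
#' expectedD(0.1, log(2))          # q = 1/6: D = 0.05 / (0.05 + 1/3)
#' @export
expectedD <- function(gamma, tInternal) {
  stopifnot(is.numeric(gamma), is.numeric(tInternal))
  if (any(gamma < 0 | gamma > 1)) stop("'gamma' must lie in [0, 1]")
  if (any(tInternal < 0)) stop("'tInternal' must be nonnegative")
  q <- exp(-tInternal) / 3
  g <- gamma * (1 - 3 * q)
  denom <- g + 2 * q
  if (any(denom == 0))
    stop("g + 2q = 0: no informative sites are possible for these parameters")
  g / denom
}

#' Genealogy-class probabilities of the simulator
#'
#' @param gamma introgression proportion.
#' @param tInternal internal branch length (coalescent units).
#' @return named numeric vector with the probabilities of the five hidden
#'   classes: `introgressed`, `ils_abba`, `ils_baba`, `ils_bbaa`,
#'   `concordant`. They sum to 1.
#' @export
classProbabilities <- function(gamma, tInternal) {
  q <- exp(-tInternal) / 3
  g <- gamma * (1 - 3 * q)
  conc <- 1 - g - 3 * q
  if (conc < -1e-12) stop("g + 3q > 1: invalid mixture")
  c(introgressed = g, ils_abba = q, ils_baba = q, ils_bbaa = q,
    concordant = max(conc, 0))
}

# hidden class -> which site pattern all its informative sites show
.classPattern <- c(introgressed = "ABBA", ils_abba = "ABBA",
                   ils_baba = "BABA", ils_bbaa = "BBAA",
                   concordant = "BBAA")

.drawLocusTruth <- function(config) {
  probs <- classProbabilities(config@gamma, config@tInternal)
  n <- config@nLoci
  cls <- sample(names(probs), n, replace = TRUE, prob = probs)
  nSites <- rpois(n, config@mutRate * config@sitesPerLocus)
  selected <- runif(n) < config@fracSelected
  data.frame(
    locus_id = sprintf("locus%05d", seq_len(n)),
    class = cls,
    omega = ifelse(selected, config@omegaSelected, 1),
    n_informative_sites = nSites,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-locus site-pattern counts
#'
#' Draws each locus's hidden genealogy class from the mixture in
#' [classProbabilities()], then assigns it a Poisson number of informative
#' sites (mean `mutRate * sitesPerLocus`), all showing the class's pattern:
#' introgressed and `ils_abba` loci contribute ABBA sites, `ils_baba` BABA,
#' and `ils_bbaa` and concordant loci BBAA.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `truth` (locus_id, class, omega, n_informative_sites)
#'   and `counts`, a per-block pattern-count table suitable for
#'   [dFromCounts()] / [dTest()] (block_id, c_abba, c_baba, c_bbaa, n_sites).
#' @examples
#' sim <- simulateLocusPatterns(simulationConfig(nLoci = 200, seed = 7))
#' head(sim$counts)
#' @export
simulateLocusPatterns <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed + 101L)
  truth <- .drawLocusTruth(config)
  pat <- .classPattern[truth$class]
  counts <- data.frame(
    block_id = truth$locus_id,
    c_abba = ifelse(pat == "ABBA", truth$n_informative_sites, 0L),
    c_baba = ifelse(pat == "BABA", truth$n_informative_sites, 0L),
    c_bbaa = ifelse(pat == "BBAA", truth$n_informative_sites, 0L),
    n_sites = truth$n_informative_sites,
    stringsAsFactors = FALSE
  )
  list(truth = truth, counts = counts)
}

## ---- codon machinery shared with the Ka/Ks module -------------------------

.codonEnv <- new.env(parent = emptyenv())

.geneticCode <- function() {
  if (is.null(.codonEnv$code)) {
    gc <- Biostrings::GENETIC_CODE
    .codonEnv$code <- gc
    .codonEnv$sense <- names(gc)[gc != "*"]
  }
  .codonEnv$code
}

.senseCodons <- function() {
  .geneticCode()
  .codonEnv$sense
}

## ---- gene trees and sequence evolution ------------------------------------

# Nested-list gene tree over the 8 taxa. `pair` is the two taxa sharing the
# derived side of the internal branch; `third` the remaining quartet taxon;
# non-quartet taxa sit between the quartet and the outgroup.
.geneTree <- function(config, pair, third) {
  taxa <- config@taxa
  out <- config@quartet[4]
  rest <- setdiff(taxa, c(pair, third, out))
  restClade <- rest[1]
  for (r in rest[-1]) restClade <- list(restClade, r)
  list(list(list(list(pair[1], pair[2]), third), restClade), out)
}

.derivedPair <- function(class, quartet) {
  switch(class,
    introgressed = ,
    ils_abba = list(pair = quartet[c(2, 3)], third = quartet[1]),
    ils_baba = list(pair = quartet[c(1, 3)], third = quartet[2]),
    ils_bbaa = ,
    concordant = list(pair = quartet[c(1, 2)], third = quartet[3]),
    stop("unknown genealogy class: ", class))
}

# Apply `nMut` accepted substitutions to a nucleotide vector. Mutations that
# would create a stop codon are resampled; nonsynonymous changes are accepted
# with probability min(1, omega) and synonymous ones with min(1, 1/omega), so
# realized Ka/Ks tracks omega on both sides of 1. Returns the mutated vector.
.mutateSequence <- function(nt, nAttempts, omega, code) {
  if (nAttempts == 0L) return(nt)
  bases <- c("A", "C", "G", "T")
  accNon <- min(1, omega)
  accSyn <- min(1, 1 / omega)
  L <- length(nt)
  for (i in seq_len(nAttempts)) {
    repeat {
      pos <- sample.int(L, 1L)
      old <- nt[pos]
      new <- sample(setdiff(bases, old), 1L)
      cStart <- pos - (pos - 1L) %% 3L
      codon <- nt[cStart:(cStart + 2L)]
      newCodon <- codon
      newCodon[(pos - cStart) + 1L] <- new
      aaOld <- code[paste(codon, collapse = "")]
      aaNew <- code[paste(newCodon, collapse = "")]
      if (aaNew == "*") next              # stop codon: resample the attempt
      acc <- if (aaNew == aaOld) accSyn else accNon
      if (runif(1) <= acc) nt[pos] <- new
      break                               # selection rejection is final
    }
  }
  nt
}

.evolveTree <- function(node, seq, rate, omega, code, sink) {
  if (is.character(node)) {
    sink[[node]] <- seq
    return(sink)
  }
  for (child in node) {
    childSeq <- .mutateSequence(seq, rpois(1L, rate), omega, code)
    sink <- .evolveTree(child, childSeq, rate, omega, code, sink)
  }
  sink
}

#' Simulate ortholog-cluster codon alignments
#'
#' For each locus the hidden genealogy class is drawn as in
#' [simulateLocusPatterns()]; a root codon sequence of sense codons is then
#' evolved down the corresponding 8-taxon gene tree. Substitutions creating
#' stop codons are rejected and resampled, so every simulated CDS stays
#' translatable; nonsynonymous changes are accepted with relative probability
#' `min(1, omega)` and synonymous ones with `min(1, 1/omega)`, so selected
#' loci (`omega > 1`) show inflated Ka/Ks. Output alignments are gap-free and
#' columnwise homologous: no aligner is needed downstream.
#'
#' @param config a [SimulationConfig-class]; `sitesPerLocus` must be a
#'   multiple of 3.
#' @param edgeLength expected substitution attempts per site on each tree
#'   edge (default 0.02 keeps pairwise divergence moderate and far from
#'   saturation).
#' @return list with `alignments` (named list of [Biostrings::DNAStringSet]
#'   objects, one per cluster, 8 taxa each) and `truth` (per-locus class and
#'   omega).
#' @examples
#' sim <- simulateClusterAlignments(simulationConfig(nLoci = 3, seed = 2))
#' sim$alignments[[1]]
#' @export
simulateClusterAlignments <- function(config, edgeLength = 0.02) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed + 202L)
  code <- .geneticCode()
  sense <- .senseCodons()
  truth <- .drawLocusTruth(config)
  nCodon <- config@sitesPerLocus %/% 3L
  rate <- edgeLength * config@sitesPerLocus
  alignments <- vector("list", config@nLoci)
  names(alignments) <- truth$locus_id
  for (i in seq_len(config@nLoci)) {
    root <- unlist(strsplit(paste(sample(sense, nCodon, replace = TRUE),
                                  collapse = ""), ""))
    dp <- .derivedPair(truth$class[i], config@quartet)
    tree <- .geneTree(config, dp$pair, dp$third)
    seqs <- .evolveTree(tree, root, rate, truth$omega[i], code,
                        sink = list())
    seqs <- seqs[config@taxa]
    alignments[[i]] <- Biostrings::DNAStringSet(
      setNames(vapply(seqs, paste, "", collapse = ""), config@taxa))
  }
  list(alignments = alignments, truth = truth)
}

#' Simulate a windowed derived-allele-frequency table
#'
#' Emits SNP rows along one synthetic chromosome for the four quartet
#' populations. A contiguous block of windows (fraction `tractFrac`) is
#' marked as an introgressed tract; inside the tract, per-SNP hidden classes
#' are drawn from the mixture with the config's `gamma`, outside with
#' `gamma = 0` (pure ILS null). Populations on the derived side of a SNP's
#' class have true derived-allele frequency `pCarrier`, the others `pOther`;
#' observed frequencies are binomial with `nChromPerPop` haplotypes.
#'
#' @param config a [SimulationConfig-class].
#' @param nWindows number of `windowSize`-bp windows on the chromosome.
#' @param snpsPerWindow expected SNPs per window (Poisson).
#' @param tractFrac fraction of windows inside the introgressed tract; with
#'   `gamma = 0` the tract has no effect and the whole chromosome is null.
#' @param pCarrier,pOther true derived-allele frequencies for populations
#'   carrying / not carrying the derived state of the SNP's class.
#' @return list with `snps` (data frame: chrom, pos (0-based), pop,
#'   derived_freq, n_chrom), and `truth` (per-window data frame: chrom,
#'   start, end, introgressed flag).
#' @examples
#' sim <- simulateWindowFrequencies(simulationConfig(gamma = 0.5, seed = 3),
#'                                  nWindows = 10)
#' head(sim$snps)
#' @export
simulateWindowFrequencies <- function(config, nWindows = 100L,
                                      snpsPerWindow = 50,
                                      tractFrac = 0.2,
                                      pCarrier = 0.9, pOther = 0.05) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed + 303L)
  w <- config@windowSize
  nWindows <- as.integer(nWindows)
  nTract <- as.integer(round(tractFrac * nWindows))
  tractStart <- if (nTract > 0L) sample.int(nWindows - nTract + 1L, 1L) else 1L
  tract <- if (nTract > 0L) seq(tractStart, tractStart + nTract - 1L) else integer(0)

  pops <- config@quartet
  nchr <- config@nChromPerPop
  rows <- vector("list", nWindows)
  for (k in seq_len(nWindows)) {
    nSnp <- rpois(1L, snpsPerWindow)
    if (nSnp == 0L) next
    pos <- sort(sample.int(w, nSnp, replace = FALSE)) - 1L + (k - 1L) * w
    gammaHere <- if (k %in% tract) config@gamma else 0
    probs <- classProbabilities(gammaHere, config@tInternal)
    cls <- sample(names(probs), nSnp, replace = TRUE, prob = probs)
    # carrier matrix: nSnp x 4 (TRUE where the population is on the derived side)
    carrier <- matrix(FALSE, nSnp, 4L)
    carrier[, 3L] <- cls %in% c("introgressed", "ils_abba", "ils_baba")
    carrier[, 2L] <- cls %in% c("introgressed", "ils_abba", "ils_bbaa",
                                "concordant")
    carrier[, 1L] <- cls %in% c("ils_baba", "ils_bbaa", "concordant")
    pTrue <- ifelse(carrier, pCarrier, pOther)
    freq <- matrix(rbinom(nSnp * 4L, nchr, pTrue), nSnp, 4L) / nchr
    rows[[k]] <- data.frame(
      chrom = "chr1",
      pos = rep(pos, each = 4L),
      pop = rep(pops, times = nSnp),
      derived_freq = as.vector(t(freq)),
      n_chrom = nchr,
      stringsAsFactors = FALSE
    )
  }
  snps <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(snps) <- NULL
  truth <- data.frame(
    chrom = "chr1",
    start = (seq_len(nWindows) - 1L) * w,
    end = seq_len(nWindows) * w,
    introgressed = seq_len(nWindows) %in% tract
  )
  list(snps = snps, truth = truth)
}

## ---- writers ---------------------------------------------------------------

#' Write simulated clusters, truth and SNP tables to disk
#'
#' `writeClusterFasta()` writes one aligned FASTA per cluster;
#' `writeTruthTable()` and `writeSnpTable()` write tab-separated tables with
#' header rows.
#'
#' @param alignments named list of `DNAStringSet` alignments.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @rdname simulationIO
#' @export
writeClusterFasta <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(alignments), ".fasta"))
  for (i in seq_along(alignments))
    Biostrings::writeXStringSet(alignments[[i]], paths[i])
  invisible(paths)
}

#' @param truth a truth data frame from a simulator.
#' @param path output file path.
#' @rdname simulationIO
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param snps SNP frequency data frame (chrom, pos, pop, derived_freq,
#'   n_chrom).
#' @rdname simulationIO
#' @export
writeSnpTable <- function(snps, path) {
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP derived-allele-frequency table
#'
#' Reads the tab-separated table written by [writeSnpTable()] (columns
#' chrom, pos, pop, derived_freq, n_chrom; 0-based positions) and checks its
#' invariants.
#'
#' @param path file path.
#' @return a validated data frame.
#' @export
readSnpTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "pop", "derived_freq", "n_chrom")
  if (!all(need %in% names(x)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  if (any(x$pos < 0)) stop("negative positions in SNP table")
  if (any(x$derived_freq < 0 | x$derived_freq > 1))
    stop("derived_freq outside [0, 1]")
  x
}
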