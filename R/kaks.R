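## Pairwise Ka/Ks screening with Nei-Gojobori (1986) counting:
## degeneracy-based site counting, path-averaged substitution counting with
## stop-codon paths excluded, Jukes-Cantor correction. Candidate filtering,
## branch-site test-plan enumeration and BH FDR utilities live here too.

# permutations of 1..k for k <= 3 (a codon pair differs at at most 3 positions)
.perms <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Per-codon synonymous site count: each of the 3 positions contributes
# f = (synonymous non-stop changes) / (non-stop changes); position weight is
# 1, so S + N = 3 * codons.
.buildSiteTable <- function() {
  code <- .geneticCode()
  sense <- .senseCodons()
  bases <- c("A", "C", "G", "T")
  s <- setNames(numeric(length(sense)), sense)
  for (codon in sense) {
    nt <- strsplit(codon, "")[[1]]
    for (pos in 1:3) {
      syn <- 0L; counted <- 0L
      for (b in setdiff(bases, nt[pos])) {
        alt <- nt; alt[pos] <- b
        aa <- code[paste(alt, collapse = "")]
        if (aa == "*") next
        counted <- counted + 1L
        if (aa == code[codon]) syn <- syn + 1L
      }
      if (counted > 0L) s[codon] <- s[codon] + syn / counted
    }
  }
  s
}

# Path-averaged (sd, nd) for every ordered sense-codon pair. Paths through
# stop codons are excluded; if every ordering is blocked the pair is NA
# (codon skipped and flagged downstream).
.buildPairTables <- function() {
  code <- .geneticCode()
  sense <- .senseCodons()
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- matrix(0, n, n, dimnames = list(sense, sense))
  split3 <- strsplit(sense, "")
  names(split3) <- sense
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) next
      a <- split3[[i]]; b <- split3[[j]]
      diffPos <- which(a != b)
      k <- length(diffPos)
      if (k == 0L) next
      sTot <- 0; nTot <- 0; nValid <- 0L
      for (perm in .perms[[k]]) {
        cur <- a; s <- 0L; ns <- 0L; valid <- TRUE
        for (step in perm) {
          pos <- diffPos[step]
          nxt <- cur; nxt[pos] <- b[pos]
          aaNext <- code[paste(nxt, collapse = "")]
          if (aaNext == "*") { valid <- FALSE; break }
          if (aaNext == code[paste(cur, collapse = "")]) s <- s + 1L
          else ns <- ns + 1L
          cur <- nxt
        }
        if (valid) { sTot <- sTot + s; nTot <- nTot + ns; nValid <- nValid + 1L }
      }
      if (nValid == 0L) {
        sd[i, j] <- sd[j, i] <- NA_real_
        nd[i, j] <- nd[j, i] <- NA_real_
      } else {
        sd[i, j] <- sd[j, i] <- sTot / nValid
        nd[i, j] <- nd[j, i] <- nTot / nValid
      }
    }
  }
  list(sd = sd, nd = nd)
}

.ng86Tables <- function() {
  if (is.null(.codonEnv$siteTable)) {
    .codonEnv$siteTable <- .buildSiteTable()
    pt <- .buildPairTables()
    .codonEnv$sdTable <- pt$sd
    .codonEnv$ndTable <- pt$nd
  }
  list(sites = .codonEnv$siteTable, sd = .codonEnv$sdTable,
       nd = .codonEnv$ndTable)
}

.splitCodons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3L != 0L)
    stop("sequence length must be a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' NG86 synonymous and nonsynonymous site counts
#'
#' Each codon position contributes the fraction of its single-base changes
#' (changes creating stop codons excluded from numerator and denominator)
#' that are synonymous; `S` sums these fractions over all positions and
#' `N = 3 * codons - S`.
#'
#' @param codonSeq a stop-free coding sequence (string), length a multiple
#'   of 3. Whitespace is ignored.
#' @return named numeric vector `c(S = ..., N = ...)`.
#' @examples
#' ng86Sites("ATG")             # Met has no synonymous neighbour: S = 0
#' ng86Sites("TTT GCA ATG GGG") # S = 7/3
#' @export
ng86Sites <- function(codonSeq) {
  tab <- .ng86Tables()
  codons <- .splitCodons(codonSeq)
  bad <- which(!codons %in% names(tab$sites))
  if (length(bad))
    stop("internal stop or invalid codon at codon index ", bad[1],
         " ('", codons[bad[1]], "')")
  S <- sum(tab$sites[codons])
  c(S = S, N = 3 * length(codons) - S)
}

#' NG86 observed substitution counts for a codon pair
#'
#' For each codon pair differing at `k` positions, synonymous/nonsynonymous
#' assignments are averaged over all `k!` orderings of single-base steps;
#' orderings passing through a stop codon are excluded. Codons for which
#' every ordering is blocked are skipped and counted.
#'
#' @param seqA,seqB aligned, gap-free, stop-free coding sequences of equal
#'   length (multiple of 3).
#' @return list with `sd`, `nd` (averaged synonymous / nonsynonymous
#'   differences) and `nSkipped`.
#' @examples
#' ng86Substitutions("AAA", "AAG")  # one synonymous step
#' @export
ng86Substitutions <- function(seqA, seqB) {
  tab <- .ng86Tables()
  a <- .splitCodons(seqA); b <- .splitCodons(seqB)
  if (length(a) != length(b)) stop("sequences differ in codon length")
  for (side in list(a, b)) {
    bad <- which(!side %in% names(tab$sites))
    if (length(bad))
      stop("internal stop or invalid codon at codon index ", bad[1])
  }
  ia <- match(a, rownames(tab$sd)); ib <- match(b, colnames(tab$sd))
  sdv <- tab$sd[cbind(ia, ib)]
  ndv <- tab$nd[cbind(ia, ib)]
  skipped <- is.na(sdv)
  list(sd = sum(sdv[!skipped]), nd = sum(ndv[!skipped]),
       nSkipped = sum(skipped))
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`. Proportions at or beyond the 3/4
#' saturation boundary return `NA` (callers flag these as saturated).
#'
#' @param p observed difference proportion(s) in `[0, 1]`.
#' @return corrected distance(s); `NA` where `p >= 3/4`.
#' @examples
#' jcCorrect(3 / 7)  # 0.6355
#' @export
jcCorrect <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

#' Pairwise Ka/Ks (NG86 with Jukes-Cantor correction)
#'
#' Removes codon columns containing gaps in either sequence, counts sites
#' and path-averaged substitutions, applies the Jukes-Cantor correction and
#' reports `ratio = Ka / Ks`. Site counts are averaged over the two
#' sequences, the standard NG86 convention.
#'
#' @param seqA,seqB aligned coding sequences of equal length (strings;
#'   `-` gaps allowed, removed pairwise per codon column).
#' @param idA,idB sequence identifiers carried into the result.
#' @param minFragment gap-free fragments shorter than this many bp are
#'   flagged `too_short` (default 100).
#' @return one-row data frame: id_a, id_b, aligned_bp, S, N, sd, nd, ka, ks,
#'   ratio, flags. `ratio` is `NA` when `ks` is 0 (`ks_zero`) or either rate
#'   is saturated (`saturated`), except that `ka = 0` with `ks > 0` gives
#'   `ratio = 0`.
#' @examples
#' kaks("TTTGCAATGGGG", "TTCGCAATGGGG")  # Ka = 0, Ks = 0.6355
#' @export
kaks <- function(seqA, seqB, idA = "a", idB = "b", minFragment = 100L) {
  a <- .splitCodons(seqA); b <- .splitCodons(seqB)
  if (length(a) != length(b)) stop("sequences differ in codon length")
  hasGap <- grepl("-", a, fixed = TRUE) | grepl("-", b, fixed = TRUE)
  a <- a[!hasGap]; b <- b[!hasGap]
  flags <- character(0)
  alignedBp <- 3L * length(a)
  if (alignedBp < minFragment) flags <- c(flags, "too_short")
  if (length(a) == 0L)
    return(data.frame(id_a = idA, id_b = idB, aligned_bp = 0L,
                      S = NA_real_, N = NA_real_, sd = NA_real_,
                      nd = NA_real_, ka = NA_real_, ks = NA_real_,
                      ratio = NA_real_,
                      flags = paste(c(flags, "empty"), collapse = ";"),
                      stringsAsFactors = FALSE))
  sitesA <- ng86Sites(paste(a, collapse = ""))
  sitesB <- ng86Sites(paste(b, collapse = ""))
  S <- (sitesA["S"] + sitesB["S"]) / 2
  N <- (sitesA["N"] + sitesB["N"]) / 2
  subs <- ng86Substitutions(paste(a, collapse = ""), paste(b, collapse = ""))
  if (subs$nSkipped > 0) flags <- c(flags, "codons_skipped")
  if (S == 0 || N == 0) {
    flags <- c(flags, "no_sites")
    ka <- ks <- ratio <- NA_real_
  } else {
    ps <- subs$sd / S
    pn <- subs$nd / N
    ks <- jcCorrect(min(ps, 1))
    ka <- jcCorrect(min(pn, 1))
    if (is.na(ks) || is.na(ka)) {
      flags <- c(flags, "saturated")
      ratio <- NA_real_
    } else if (ks == 0) {
      flags <- c(flags, "ks_zero")
      ratio <- NA_real_
    } else {
      ratio <- ka / ks
    }
  }
  data.frame(id_a = idA, id_b = idB, aligned_bp = alignedBp,
             S = unname(S), N = unname(N), sd = subs$sd, nd = subs$nd,
             ka = unname(ka), ks = unname(ks), ratio = unname(ratio),
             flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' All pairwise Ka/Ks results for one cluster
#'
#' @param alignment a `DNAStringSet` or character matrix of one ortholog
#'   cluster (aligned CDS, one row per species).
#' @param clusterId identifier carried into the result.
#' @param minFragment passed to [kaks()].
#' @return data frame with `choose(n, 2)` rows (28 for 8 species), columns
#'   as in [kaks()] plus `cluster_id`.
#' @export
clusterKaKs <- function(alignment, clusterId = "cluster1", minFragment = 100L) {
  m <- .alignmentMatrix(alignment)
  seqs <- apply(m, 1, paste, collapse = "")
  taxa <- names(seqs)
  pairs <- combn(taxa, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    kaks(seqs[pairs[1, i]], seqs[pairs[2, i]],
         idA = pairs[1, i], idB = pairs[2, i], minFragment = minFragment)
  })
  out <- do.call(rbind, rows)
  cbind(cluster_id = clusterId, out, stringsAsFactors = FALSE)
}

#' Enumerate the pairwise Ka/Ks screening plan
#'
#' One planned comparison per (cluster, unordered species pair): a set of
#' `m` clusters over `n` species yields `m * choose(n, 2)` comparisons
#' (4,042 eight-species clusters give 113,176).
#'
#' @param clusterIds character vector of cluster identifiers.
#' @param taxa species labels (default the package's eight study taxa).
#' @return data frame: cluster_id, sp_a, sp_b; deterministic order
#'   (clusters as given, pairs in `combn` order).
#' @export
kaksPlan <- function(clusterIds,
                     taxa = c("sara", "hortense", "erato", "doris",
                              "cydno", "melpomene", "hecale", "iulia")) {
  pairs <- combn(taxa, 2)
  nP <- ncol(pairs)
  data.frame(
    cluster_id = rep(clusterIds, each = nP),
    sp_a = rep(pairs[1, ], times = length(clusterIds)),
    sp_b = rep(pairs[2, ], times = length(clusterIds)),
    stringsAsFactors = FALSE
  )
}

#' Screen Ka/Ks results for positive-selection candidates
#'
#' Retains (cluster, pair) rows with `ratio > 1`, a gap-free aligned
#' fragment of at least `minFragment` bp, and `ks` below the saturation cap.
#' These automated filters operationalize the manual removal of poor
#' alignments.
#'
#' @param kaksTable data frame of [clusterKaKs()] rows (must include
#'   cluster_id, ratio, aligned_bp, ks, flags).
#' @param minFragment minimum gap-free fragment length in bp (default 100).
#' @param maxKs saturation cap on `ks` (default 2.0).
#' @return list with `table` (the input plus a logical `retained` column),
#'   `candidates` (retained rows) and `clusters` (distinct retained cluster
#'   ids).
#' @export
screenCandidates <- function(kaksTable, minFragment = 100L, maxKs = 2.0) {
  if (nrow(kaksTable) == 0L)
    return(list(table = kaksTable, candidates = kaksTable,
                clusters = character(0)))
  retained <- !is.na(kaksTable$ratio) & kaksTable$ratio > 1 &
    kaksTable$aligned_bp >= minFragment &
    !is.na(kaksTable$ks) & kaksTable$ks < maxKs &
    !grepl("saturated", kaksTable$flags)
  tab <- cbind(kaksTable, retained = retained)
  list(table = tab, candidates = tab[retained, , drop = FALSE],
       clusters = unique(tab$cluster_id[retained]))
}

#' Fixed eight-taxon species topology
#'
#' The transcriptome species tree used for branch-site test planning:
#' `(((((sara,hortense),erato),doris),((cydno,melpomene),hecale)),iulia)`.
#'
#' @return an [ape::read.tree()] `phylo` object.
#' @export
speciesTopology <- function() {
  ape::read.tree(text =
    "(((((sara,hortense),erato),doris),((cydno,melpomene),hecale)),iulia);")
}

#' Default foreground branches for branch-site planning
#'
#' Eight terminal branches plus four internal nodes: (sara, hortense),
#' (sara, hortense, erato), (cydno, melpomene) and (cydno, melpomene,
#' hecale).
#'
#' @return named list of tip-label vectors; length-1 entries are terminal
#'   branches.
#' @export
defaultForegrounds <- function() {
  tips <- c("sara", "hortense", "erato", "doris", "cydno", "melpomene",
            "hecale", "iulia")
  fg <- c(as.list(tips),
          list(c("sara", "hortense"),
               c("sara", "hortense", "erato"),
               c("cydno", "melpomene"),
               c("cydno", "melpomene", "hecale")))
  names(fg) <- c(tips, "sara+hortense", "sara+hortense+erato",
                 "cydno+melpomene", "cydno+melpomene+hecale")
  fg
}

.tagTree <- function(tree, tips) {
  t2 <- tree
  if (length(tips) == 1L) {
    t2$tip.label[t2$tip.label == tips] <- paste0(tips, "#1")
  } else {
    node <- ape::getMRCA(t2, tips)
    lab <- rep("", t2$Nnode)
    lab[node - ape::Ntip(t2)] <- "#1"
    t2$node.label <- lab
  }
  ape::write.tree(t2)
}

#' Enumerate the branch-site test plan
#'
#' One planned likelihood test per (candidate cluster, foreground branch);
#' 276 clusters with the default 12 foregrounds give 3,312 rows. The
#' likelihood engine itself is external; the plan carries a foreground-
#' tagged newick for it. Internal foregrounds must be monophyletic on the
#' given topology.
#'
#' @param candidateClusters character vector of cluster ids.
#' @param tree a `phylo` species topology (default [speciesTopology()]).
#' @param foregrounds named list of tip-label vectors (default
#'   [defaultForegrounds()]).
#' @return data frame: cluster_id, foreground, n_tips, tagged_tree;
#'   deterministic order (clusters as given, then foregrounds).
#' @export
enumerateBranchTests <- function(candidateClusters, tree = speciesTopology(),
                                 foregrounds = defaultForegrounds()) {
  taggedTrees <- character(length(foregrounds))
  for (i in seq_along(foregrounds)) {
    tips <- foregrounds[[i]]
    bad <- setdiff(tips, tree$tip.label)
    if (length(bad))
      stop("foreground '", names(foregrounds)[i],
           "' has tips absent from the topology: ", paste(bad, collapse = ", "))
    if (length(tips) > 1L) {
      node <- ape::getMRCA(tree, tips)
      clade <- ape::extract.clade(tree, node)$tip.label
      if (!setequal(clade, tips))
        stop("foreground '", names(foregrounds)[i],
             "' is not a clade on the topology (MRCA spans: ",
             paste(clade, collapse = ", "), ")")
    }
    taggedTrees[i] <- .tagTree(tree, tips)
  }
  nF <- length(foregrounds)
  data.frame(
    cluster_id = rep(candidateClusters, each = nF),
    foreground = rep(names(foregrounds), times = length(candidateClusters)),
    n_tips = rep(lengths(foregrounds), times = length(candidateClusters)),
    tagged_tree = rep(taggedTrees, times = length(candidateClusters)),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Finds the largest `k` with `p_(k) <= k * q / m`; the adjusted threshold
#' is `p_(k)` and all p-values at or below it are rejected.
#'
#' @param pValues numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate in `(0, 1)` (default 0.01).
#' @return list with `rejected` (logical, input order), `threshold`
#'   (`p_(k)`, or `NA` when nothing is rejected) and `nRejected`.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)  # all four rejected
#' @export
bhFdr <- function(pValues, q = 0.01) {
  if (length(pValues) == 0L)
    return(list(rejected = logical(0), threshold = NA_real_, nRejected = 0L))
  if (any(pValues < 0 | pValues > 1)) stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  m <- length(pValues)
  ps <- sort(pValues)
  k <- which(ps <= seq_len(m) * q / m)
  if (length(k) == 0L)
    return(list(rejected = rep(FALSE, m), threshold = NA_real_,
                nRejected = 0L))
  thr <- ps[max(k)]
  rejected <- pValues <= thr
  list(rejected = rejected, threshold = thr, nRejected = sum(rejected))
}
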