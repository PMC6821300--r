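## Patterson's D in two estimator forms, with leave-one-out jackknife
## standard errors and two-tailed z tests.
##
## Both estimators are ratios of sums: numerators and denominators are
## accumulated over blocks (ortholog clusters in count mode, 50-kb windows
## in frequency mode) before dividing. This is not the mean of per-block D
## values, and the jackknife recomputes the full ratio with each block
## deleted.

#' Tally site patterns for one block
#'
#' @param patterns character vector of per-site pattern labels (from
#'   [classifyPattern()] / [quartetSitePatterns()]).
#' @param blockId identifier for the block (cluster or window).
#' @return one-row data frame: block_id, c_abba, c_baba, c_bbaa, n_sites
#'   (`n_sites` counts all classified sites including uninformative ones).
#' @examples
#' countPatterns(c("ABBA", "BABA", "ABBA"), "cluster1")
#' @export
countPatterns <- function(patterns, blockId = "block1") {
  data.frame(
    block_id = blockId,
    c_abba = sum(patterns == "ABBA"),
    c_baba = sum(patterns == "BABA"),
    c_bbaa = sum(patterns == "BBAA"),
    n_sites = length(patterns),
    stringsAsFactors = FALSE
  )
}

#' D from per-block ABBA/BABA counts
#'
#' The count-form estimator
#' \deqn{D = \frac{\sum_i C_{ABBA}(i) - C_{BABA}(i)}
#'                {\sum_i C_{ABBA}(i) + C_{BABA}(i)}}
#' summed over blocks before dividing (ratio of sums, not mean of per-block
#' ratios).
#'
#' @param blocks data frame with columns `c_abba` and `c_baba`, one row per
#'   block.
#' @return list with `numerator`, `denominator`, `d` and `flags`
#'   (`"undefined"` when the denominator is zero, in which case `d` is `NA`).
#' @examples
#' dFromCounts(data.frame(c_abba = c(2, 0, 2), c_baba = c(0, 2, 0)))$d
#' @export
dFromCounts <- function(blocks) {
  if (nrow(blocks) < 1L) stop("at least one block is required")
  num <- sum(blocks$c_abba) - sum(blocks$c_baba)
  den <- sum(blocks$c_abba) + sum(blocks$c_baba)
  if (den == 0)
    return(list(numerator = num, denominator = den, d = NA_real_,
                flags = "undefined"))
  list(numerator = num, denominator = den, d = num / den,
       flags = character(0))
}

#' D from derived-allele frequencies
#'
#' The frequency-form estimator: for SNP \eqn{i} with derived-allele
#' frequencies \eqn{\hat p_{i1}, \ldots, \hat p_{i4}} in populations
#' \eqn{(P_1, P_2, P_3, O)},
#' \deqn{ABBA_i = (1-\hat p_{i1})\,\hat p_{i2}\,\hat p_{i3}\,(1-\hat p_{i4}),
#'  \quad BABA_i = \hat p_{i1}\,(1-\hat p_{i2})\,\hat p_{i3}\,(1-\hat p_{i4})}
#' and \eqn{D = \sum_i (ABBA_i - BABA_i) / \sum_i (ABBA_i + BABA_i)}.
#' With all frequencies in `{0, 1}` this reduces exactly to the count form
#' on the same polarized sites.
#'
#' @param freqs numeric matrix or data frame with 4 columns ordered
#'   `(P1, P2, P3, O)`, one row per SNP; entries in `[0, 1]`.
#' @return list with per-SNP `abba` and `baba` weights, `numerator`,
#'   `denominator`, `d` and `flags`.
#' @examples
#' dFromFrequencies(rbind(c(0.2, 0.8, 1.0, 0.0)))$d  # 0.60 / 0.68
#' @export
dFromFrequencies <- function(freqs) {
  p <- as.matrix(freqs)
  if (ncol(p) != 4L) stop("frequency matrix must have 4 columns (P1, P2, P3, O)")
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  abba <- (1 - p[, 1]) * p[, 2] * p[, 3] * (1 - p[, 4])
  baba <- p[, 1] * (1 - p[, 2]) * p[, 3] * (1 - p[, 4])
  num <- sum(abba - baba)
  den <- sum(abba + baba)
  list(abba = abba, baba = baba, numerator = num, denominator = den,
       d = if (den == 0) NA_real_ else num / den,
       flags = if (den == 0) "undefined" else character(0))
}

#' Leave-one-out jackknife SE of a ratio-of-sums
#'
#' Recomputes the ratio with block \eqn{i} deleted,
#' \eqn{\theta_{(i)} = (N - n_i) / (Dn - d_i)}, and returns the Tukey
#' delete-one standard error
#' \deqn{SE = \sqrt{\frac{n-1}{n} \sum_i (\theta_{(i)} - \bar\theta)^2}.}
#' Deletions that leave a zero denominator are skipped with a warning and
#' `n` adjusted.
#'
#' @param num per-block numerator contributions.
#' @param den per-block denominator contributions.
#' @return list with `se`, `nUsed` (blocks contributing valid deletions) and
#'   `thetas` (the delete-one estimates).
#' @examples
#' b <- data.frame(c_abba = c(2, 0, 2), c_baba = c(0, 2, 0))
#' jackknifeSE(b$c_abba - b$c_baba, b$c_abba + b$c_baba)$se  # 2/3
#' @export
jackknifeSE <- function(num, den) {
  n <- length(num)
  if (n < 2L) stop("insufficient_blocks: jackknife needs >= 2 blocks")
  N <- sum(num); Dn <- sum(den)
  denLeft <- Dn - den
  ok <- denLeft != 0
  if (!all(ok))
    warning(sum(!ok), " delete-one replicate(s) undefined (zero denominator); skipped")
  thetas <- (N - num[ok]) / denLeft[ok]
  m <- length(thetas)
  if (m < 2L) stop("insufficient_blocks: fewer than 2 valid delete-one replicates")
  se <- sqrt(((m - 1) / m) * sum((thetas - mean(thetas))^2))
  list(se = se, nUsed = m, thetas = thetas)
}

# shared core: per-block numerators/denominators -> DResult
.dResultFromBlocks <- function(num, den, quartet, mode) {
  flags <- character(0)
  total <- sum(den)
  d <- if (total == 0) NA_real_ else sum(num) / total
  if (total == 0) flags <- c(flags, "undefined")
  se <- NA_real_
  if (!is.na(d) && length(num) >= 2L) {
    jk <- tryCatch(jackknifeSE(num, den), error = function(e) NULL)
    if (!is.null(jk)) se <- jk$se else flags <- c(flags, "se_unavailable")
  } else if (length(num) < 2L) {
    flags <- c(flags, "se_unavailable")
  }
  z <- p <- NA_real_
  if (!is.na(d) && !is.na(se)) {
    if (se == 0 && d != 0) {
      z <- Inf * sign(d); p <- 0; flags <- c(flags, "degenerate")
    } else if (se == 0 && d == 0) {
      flags <- c(flags, "untestable")
    } else {
      z <- d / se
      p <- 2 * (1 - pnorm(abs(z)))
    }
  }
  if (is.null(names(quartet))) names(quartet) <- c("P1", "P2", "P3", "O")
  new("DResult", quartet = quartet, mode = mode,
      d = if (is.na(d)) NA_real_ else d, se = se, z = z, p = p,
      nBlocks = length(num), numerator = sum(num), denominator = total,
      flags = flags)
}

#' D-statistic z test over blocks
#'
#' Combines the ratio-of-sums estimator, the leave-one-out jackknife SE and
#' a two-tailed z test (`z = D / SE`, `p = 2 (1 - Phi(|z|))`) into one
#' [DResult-class]. Significance stars in `show()` follow the usual figure
#' convention (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param blocks in `"counts"` mode, a data frame with per-block `c_abba`
#'   and `c_baba` columns; in `"frequencies"` mode, a data frame or matrix
#'   with per-block summed `abba` and `baba` weight columns.
#' @param quartet labels `(P1, P2, P3, O)`.
#' @param mode `"counts"` or `"frequencies"`.
#' @return a [DResult-class].
#' @examples
#' sim <- simulateLocusPatterns(simulationConfig(nLoci = 500, gamma = 0.2,
#'                                               seed = 11))
#' dTest(sim$counts, c("P1", "P2", "P3", "O"))
#' @export
dTest <- function(blocks, quartet, mode = c("counts", "frequencies")) {
  mode <- match.arg(mode)
  if (mode == "counts") {
    num <- blocks$c_abba - blocks$c_baba
    den <- blocks$c_abba + blocks$c_baba
  } else {
    blocks <- as.data.frame(blocks)
    num <- blocks$abba - blocks$baba
    den <- blocks$abba + blocks$baba
  }
  .dResultFromBlocks(num, den, quartet, mode)
}

#' Windowed D scan from a SNP frequency table
#'
#' Computes the frequency-form D for every non-overlapping `windowSize`-bp
#' window ([assignWindows()]), with a per-window SE by delete-one jackknife
#' over the window's SNPs, and a chromosome-level D whose SE uses the
#' windows themselves as jackknife blocks.
#'
#' @param snps SNP frequency data frame (chrom, pos, pop, derived_freq,
#'   n_chrom), e.g. from [simulateWindowFrequencies()] or [readSnpTable()].
#' @param quartet population labels `(P1, P2, P3, O)`; all four must appear
#'   in the table.
#' @param windowSize window width in bp.
#' @return list with `windows` (data frame: chrom, start, end, n_snps, D,
#'   SE, z, p) and `chromosomes` (named list of [DResult-class], one per
#'   chromosome; windows with undefined D are excluded from the chromosome
#'   jackknife and counted in its flags).
#' @export
windowedD <- function(snps, quartet, windowSize = 50000L) {
  stopifnot(length(quartet) == 4L)
  missingPop <- setdiff(quartet, unique(snps$pop))
  if (length(missingPop))
    stop("populations absent from table: ", paste(missingPop, collapse = ", "))
  sub <- snps[snps$pop %in% quartet, , drop = FALSE]
  key <- paste(sub$chrom, sub$pos, sep = "\r")
  usnp <- unique(key)
  pmat <- matrix(NA_real_, length(usnp), 4L,
                 dimnames = list(usnp, quartet))
  for (j in seq_along(quartet)) {
    rows <- sub[sub$pop == quartet[j], ]
    pmat[paste(rows$chrom, rows$pos, sep = "\r"), j] <- rows$derived_freq
  }
  complete <- stats::complete.cases(pmat)
  pmat <- pmat[complete, , drop = FALSE]
  usnp <- usnp[complete]
  parts <- strsplit(usnp, "\r", fixed = TRUE)
  snpTab <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                       pos = as.numeric(vapply(parts, `[`, "", 2L)),
                       stringsAsFactors = FALSE)
  dw <- dFromFrequencies(pmat)
  aw <- assignWindows(snpTab, windowSize)
  win <- aw$windows
  win$D <- win$SE <- win$z <- win$p <- NA_real_
  numW <- denW <- numeric(nrow(win))
  for (k in seq_len(nrow(win))) {
    idx <- which(aw$index == k)
    a <- dw$abba[idx]; b <- dw$baba[idx]
    numW[k] <- sum(a - b); denW[k] <- sum(a + b)
    if (denW[k] > 0) {
      win$D[k] <- numW[k] / denW[k]
      if (length(idx) >= 2L) {
        jk <- tryCatch(jackknifeSE(a - b, a + b), error = function(e) NULL)
        if (!is.null(jk)) {
          win$SE[k] <- jk$se
          if (jk$se > 0) {
            win$z[k] <- win$D[k] / jk$se
            win$p[k] <- 2 * (1 - pnorm(abs(win$z[k])))
          }
        }
      }
    }
  }
  chromosomes <- list()
  for (ch in unique(win$chrom)) {
    rows <- which(win$chrom == ch)
    usable <- rows[denW[rows] > 0]
    res <- .dResultFromBlocks(numW[usable], denW[usable], quartet,
                              "frequencies")
    if (length(usable) < length(rows))
      res@flags <- c(res@flags,
                     sprintf("windows_excluded:%d", length(rows) - length(usable)))
    chromosomes[[ch]] <- res
  }
  list(windows = win, chromosomes = chromosomes)
}

#' Run a suite of quartet D tests over ortholog clusters
#'
#' For each quartet assignment, extracts polarized quartet site patterns
#' from every cluster alignment, tallies per-cluster ABBA/BABA counts
#' (clusters are the jackknife blocks) and performs the count-form z test.
#' Row order follows the quartet list.
#'
#' @param alignments named list of cluster alignments (`DNAStringSet` or
#'   character matrices with taxon rownames).
#' @param quartets list of character(4) vectors `(P1, P2, P3, O)`.
#' @return data frame with one row per quartet (P1, P2, P3, O, mode,
#'   nBlocks, numerator, denominator, D, SE, z, p, stars, flags).
#' @examples
#' sim <- simulateClusterAlignments(simulationConfig(nLoci = 30, seed = 5))
#' runDSuite(sim$alignments,
#'           list(c("sara", "hortense", "erato", "iulia")))
#' @export
runDSuite <- function(alignments, quartets) {
  taxaAvailable <- rownames(.alignmentMatrix(alignments[[1]]))
  for (q in quartets) {
    bad <- setdiff(q, taxaAvailable)
    if (length(bad))
      stop("unknown label(s) in quartet (", paste(q, collapse = ","), "): ",
           paste(bad, collapse = ", "))
  }
  rows <- lapply(quartets, function(q) {
    counts <- do.call(rbind, lapply(names(alignments), function(id) {
      countPatterns(quartetSitePatterns(alignments[[id]], q)$patterns, id)
    }))
    as.data.frame(dTest(counts, q, mode = "counts"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cluster quartet concordance
#'
#' Tallies BBAA/ABBA/BABA counts per cluster for one quartet and reports the
#' majority topology (ties are `"unresolved"`). Useful for quantifying how
#' many clusters support each resolution of a contested branch.
#'
#' @param alignments named list of cluster alignments.
#' @param quartet labels `(P1, P2, P3, O)`.
#' @return data frame: cluster_id, c_bbaa, c_abba, c_baba, majority.
#' @export
quartetConcordance <- function(alignments, quartet) {
  rows <- lapply(names(alignments), function(id) {
    pat <- quartetSitePatterns(alignments[[id]], quartet)$patterns
    cnt <- c(BBAA = sum(pat == "BBAA"), ABBA = sum(pat == "ABBA"),
             BABA = sum(pat == "BABA"))
    top <- names(cnt)[cnt == max(cnt)]
    data.frame(cluster_id = id, c_bbaa = cnt[["BBAA"]],
               c_abba = cnt[["ABBA"]], c_baba = cnt[["BABA"]],
               majority = if (length(top) == 1L) top else "unresolved",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
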