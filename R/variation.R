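## Site extraction and classification: outgroup-polarized biallelic sites
## from codon alignments, ABBA/BABA/BBAA quartet patterns, and genomic
## window assignment for the frequency-mode scan.
##
## Coordinates are 0-based half-open everywhere inside the package; 1-based
## only where an output format demands it.

.alignmentMatrix <- function(alignment) {
  if (is(alignment, "DNAStringSet")) {
    m <- as.matrix(alignment)
  } else if (is.matrix(alignment) && is.character(alignment)) {
    m <- alignment
  } else {
    stop("alignment must be a DNAStringSet or a character matrix")
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment rows must carry unique taxon names")
  toupper(m)
}

#' Extract biallelic sites from an aligned cluster
#'
#' Scans alignment columns and keeps those with exactly two distinct bases
#' among `{A, C, G, T}` across the requested taxa and no gap, `N` or other
#' ambiguity code in any of them (listwise deletion within the requested
#' taxon set only — a column unusable for one quartet may still serve
#' another). Columns with three or more alleles are excluded.
#'
#' @param alignment a [Biostrings::DNAStringSet] of equal-length sequences,
#'   or a character matrix with taxon rownames.
#' @param taxa taxa to consider (default: all rows). Typically the active
#'   quartet `(P1, P2, P3, O)`.
#' @return data frame with `position` (0-based column index) and one base
#'   column per requested taxon, in the order of `taxa`.
#' @examples
#' aln <- Biostrings::DNAStringSet(c(a = "ATGA", b = "ATGG", c = "ACGG",
#'                                   o = "ATGA"))
#' extractBiallelicSites(aln)
#' @export
extractBiallelicSites <- function(alignment, taxa = NULL) {
  m <- .alignmentMatrix(alignment)
  if (length(unique(nchar(apply(m, 1, paste, collapse = "")))) > 1L)
    stop("ragged alignment: sequences differ in length")
  if (is.null(taxa)) taxa <- rownames(m)
  missingTaxa <- setdiff(taxa, rownames(m))
  if (length(missingTaxa))
    stop("taxa not present in alignment: ", paste(missingTaxa, collapse = ", "))
  sub <- m[taxa, , drop = FALSE]
  ok <- apply(sub, 2, function(col) {
    if (any(!col %in% c("A", "C", "G", "T"))) return(FALSE)
    length(unique(col)) == 2L
  })
  idx <- which(ok)
  out <- data.frame(position = idx - 1L)
  for (t in taxa) out[[t]] <- unname(sub[t, idx])
  out
}

#' Polarize sites by the outgroup allele
#'
#' Marks taxa carrying the non-outgroup allele as derived (1) and the
#' outgroup allele as ancestral (0). Polarization always follows the
#' outgroup, even when the outgroup carries the globally rarer allele.
#' Sites where the outgroup call is missing or ambiguous are dropped and
#' counted.
#'
#' @param sites data frame from [extractBiallelicSites()] (a `position`
#'   column plus one base column per taxon).
#' @param outgroup name of the outgroup column.
#' @return list with `derived` (integer 0/1 matrix, one row per retained
#'   site, columns in the input taxon order), `position` (0-based), and
#'   `nDropped` (sites lost to an unusable outgroup call).
#' @export
polarizeSites <- function(sites, outgroup) {
  taxa <- setdiff(names(sites), "position")
  if (!outgroup %in% taxa) stop("outgroup '", outgroup, "' not among taxa")
  bases <- as.matrix(sites[, taxa, drop = FALSE])
  anc <- bases[, outgroup]
  usable <- anc %in% c("A", "C", "G", "T")
  nDropped <- sum(!usable)
  bases <- bases[usable, , drop = FALSE]
  derived <- (bases != bases[, outgroup]) * 1L
  dimnames(derived) <- list(NULL, taxa)
  list(derived = derived, position = sites$position[usable],
       nDropped = nDropped)
}

#' Classify a quartet site pattern
#'
#' Maps a derived-state vector over `(P1, P2, P3, O)` to its site pattern:
#' `(0,1,1,0)` is ABBA, `(1,0,1,0)` BABA, `(1,1,0,0)` BBAA; anything else is
#' uninformative. Only the 0/1 vector matters, never which base plays the
#' derived role.
#'
#' @param derived an integer vector of length 4, or a 4-column 0/1 matrix
#'   (one row per site), ordered `(P1, P2, P3, O)`.
#' @return character vector of labels in
#'   `{"ABBA", "BABA", "BBAA", "uninformative"}`.
#' @examples
#' classifyPattern(c(0, 1, 1, 0))  # "ABBA"
#' @export
classifyPattern <- function(derived) {
  if (is.vector(derived)) derived <- matrix(derived, nrow = 1)
  if (ncol(derived) != 4L)
    stop("derived-state vectors must have length 4 (P1, P2, P3, O)")
  key <- derived[, 1] * 8L + derived[, 2] * 4L + derived[, 3] * 2L + derived[, 4]
  out <- rep("uninformative", nrow(derived))
  out[key == 6L] <- "ABBA"    # 0110
  out[key == 10L] <- "BABA"   # 1010
  out[key == 12L] <- "BBAA"   # 1100
  out
}

#' Site patterns of one cluster for a quartet
#'
#' Convenience composition of [extractBiallelicSites()], [polarizeSites()]
#' and [classifyPattern()] restricted to the four quartet taxa.
#'
#' @param alignment a `DNAStringSet` or character matrix.
#' @param quartet labels `(P1, P2, P3, O)`; the fourth is the outgroup.
#' @return list with `patterns` (character vector, one entry per polarized
#'   biallelic quartet site) and `nDropped`.
#' @export
quartetSitePatterns <- function(alignment, quartet) {
  stopifnot(length(quartet) == 4L)
  sites <- extractBiallelicSites(alignment, taxa = quartet)
  pol <- polarizeSites(sites, outgroup = quartet[4])
  list(patterns = classifyPattern(pol$derived), nDropped = pol$nDropped)
}

#' Assign SNPs to non-overlapping genomic windows
#'
#' A SNP at 0-based position `p` belongs to the half-open window
#' `[k*w, (k+1)*w)` with `k = floor(p / w)`. Windows tile each chromosome
#' without overlap; empty windows are omitted.
#'
#' @param table data frame with at least `chrom` and `pos` (0-based bp)
#'   columns; typically a SNP frequency table.
#' @param windowSize window width in bp (`> 0`).
#' @return list with `windows` (data frame: chrom, start, end, n_snps) and
#'   `index` (integer vector mapping each input row to its row in
#'   `windows`).
#' @examples
#' tab <- data.frame(chrom = "chr1", pos = c(10, 49999, 50000, 120000))
#' assignWindows(tab, 50000)$windows
#' @export
assignWindows <- function(table, windowSize) {
  if (windowSize <= 0) stop("'windowSize' must be positive")
  if (any(table$pos < 0)) stop("negative positions are not allowed")
  k <- floor(table$pos / windowSize)
  keyAll <- paste(table$chrom, k, sep = "\r")
  keys <- unique(keyAll)
  # deterministic order: chromosome, then window start
  parts <- strsplit(keys, "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  start <- as.numeric(vapply(parts, `[`, "", 2L)) * windowSize
  ord <- order(chrom, start)
  keys <- keys[ord]
  windows <- data.frame(
    chrom = chrom[ord],
    start = start[ord],
    end = start[ord] + windowSize,
    n_snps = as.vector(table(factor(keyAll, levels = keys))),
    stringsAsFactors = FALSE
  )
  list(windows = windows, index = match(keyAll, keys))
}
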