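#' @import methods
#' @importFrom stats pnorm rbinom rpois runif setNames
#' @importFrom utils read.delim write.table combn
NULL

#' Simulation configuration
#'
#' Parameters of the generative model used to produce synthetic pipeline
#' inputs: ortholog-cluster codon alignments, per-locus site-pattern counts,
#' and windowed derived-allele-frequency tables with known ground truth.
#'
#' The hidden genealogy of each locus is drawn from a three-class mixture.
#' With \eqn{q = \exp(-t)/3} (where \eqn{t} is the internal branch length in
#' coalescent units) a locus is introgressed with probability
#' \eqn{g = \gamma (1 - 3q)}, follows each of the three incomplete-lineage-
#' sorting resolutions (ABBA, BABA, BBAA) with probability \eqn{q}, and is
#' concordant with the species tree otherwise. Under this model the expected
#' Patterson's D over many loci has the closed form \eqn{g / (g + 2q)}; see
#' [expectedD()].
#'
#' @slot nLoci number of ortholog clusters / loci to simulate.
#' @slot sitesPerLocus alignment length in nucleotides (multiple of 3).
#' @slot taxa ordered character vector of 8 taxon labels; the last one is the
#'   outgroup.
#' @slot quartet labels `(P1, P2, P3, O)` used for site-pattern truth.
#' @slot gamma probability in `[0, 1]` that a locus follows the introgression
#'   topology (P2 with P3), producing an ABBA excess.
#' @slot tInternal internal branch length in coalescent units; controls how
#'   much incomplete lineage sorting the model produces.
#' @slot mutRate expected informative-site fraction per locus.
#' @slot omegaSelected Ka/Ks ratio applied to loci under positive selection.
#' @slot fracSelected proportion of loci assigned `omegaSelected`.
#' @slot nChromPerPop haplotypes sampled per population in frequency mode.
#' @slot windowSize genomic window size in bp (default 50000).
#' @slot seed integer seed; a fixed seed gives byte-identical outputs.
#'
#' @seealso [simulationConfig()] for the user constructor.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nLoci = "integer",
    sitesPerLocus = "integer",
    taxa = "character",
    quartet = "character",
    gamma = "numeric",
    tInternal = "numeric",
    mutRate = "numeric",
    omegaSelected = "numeric",
    fracSelected = "numeric",
    nChromPerPop = "integer",
    windowSize = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@taxa) != 8L)
    msg <- c(msg, "'taxa' must contain exactly 8 labels")
  if (anyDuplicated(object@taxa))
    msg <- c(msg, "'taxa' labels must be distinct")
  if (length(object@quartet) != 4L)
    msg <- c(msg, "'quartet' must contain exactly 4 labels (P1, P2, P3, O)")
  if (!all(object@quartet %in% object@taxa))
    msg <- c(msg, "'quartet' labels must all appear in 'taxa'")
  if (length(object@gamma) != 1L || object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "'gamma' must be a probability in [0, 1]")
  if (length(object@tInternal) != 1L || object@tInternal < 0)
    msg <- c(msg, "'tInternal' must be nonnegative")
  if (object@mutRate < 0 || object@mutRate > 1)
    msg <- c(msg, "'mutRate' must be in [0, 1]")
  if (object@fracSelected < 0 || object@fracSelected > 1)
    msg <- c(msg, "'fracSelected' must be in [0, 1]")
  if (object@omegaSelected <= 0)
    msg <- c(msg, "'omegaSelected' must be positive")
  if (object@nLoci < 1L) msg <- c(msg, "'nLoci' must be >= 1")
  if (object@sitesPerLocus < 3L || object@sitesPerLocus %% 3L != 0L)
    msg <- c(msg, "'sitesPerLocus' must be a positive multiple of 3")
  if (object@nChromPerPop < 1L) msg <- c(msg, "'nChromPerPop' must be >= 1")
  if (object@windowSize < 1L) msg <- c(msg, "'windowSize' must be positive")
  # mixture weights must define a proper distribution
  q <- exp(-object@tInternal) / 3
  g <- object@gamma * (1 - 3 * q)
  if (1 - g - 3 * q < -1e-12)
    msg <- c(msg, "class probabilities g + 3q exceed 1; decrease gamma or increase tInternal")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' User-facing constructor for [SimulationConfig-class] with the package's
#' default study conditions: eight taxa (last the outgroup), a quartet of
#' three ingroup lineages plus the outgroup, introgression proportion
#' `gamma = 0.1` and internal branch `tInternal = log(2)` (so each ILS class
#' has probability 1/6).
#'
#' @param nLoci number of loci (ortholog clusters) to simulate.
#' @param sitesPerLocus alignment length in nucleotides; multiple of 3.
#' @param taxa 8 taxon labels, outgroup last.
#' @param quartet 4 labels `(P1, P2, P3, O)` drawn from `taxa`.
#' @param gamma introgression-class probability in `[0, 1]`.
#' @param tInternal internal branch length (coalescent units), `>= 0`.
#' @param mutRate expected informative-site fraction per locus.
#' @param omegaSelected Ka/Ks applied to selected loci (`> 0`).
#' @param fracSelected fraction of loci that are selected.
#' @param nChromPerPop haplotypes per population for frequency mode.
#' @param windowSize window size in bp.
#' @param seed integer seed.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nLoci = 100, gamma = 0.2, seed = 1)
#' expectedD(introgressionGamma(cfg), tInternal(cfg))
#' @export
simulationConfig <- function(nLoci = 1000L,
                             sitesPerLocus = 900L,
                             taxa = c("sara", "hortense", "erato", "doris",
                                      "cydno", "melpomene", "hecale", "iulia"),
                             quartet = c("sara", "hortense", "erato", "iulia"),
                             gamma = 0.1,
                             tInternal = log(2),
                             mutRate = 0.02,
                             omegaSelected = 5,
                             fracSelected = 0.05,
                             nChromPerPop = 10L,
                             windowSize = 50000L,
                             seed = 1L) {
  new("SimulationConfig",
      nLoci = as.integer(nLoci), sitesPerLocus = as.integer(sitesPerLocus),
      taxa = as.character(taxa), quartet = as.character(quartet),
      gamma = as.numeric(gamma), tInternal = as.numeric(tInternal),
      mutRate = as.numeric(mutRate),
      omegaSelected = as.numeric(omegaSelected),
      fracSelected = as.numeric(fracSelected),
      nChromPerPop = as.integer(nChromPerPop),
      windowSize = as.integer(windowSize), seed = as.integer(seed))
}

#' D-statistic test result
#'
#' Holds one four-taxon D-statistic: the quartet assignment, the estimator
#' mode (`"counts"` for per-cluster ABBA/BABA tallies, `"frequencies"` for
#' the derived-allele-frequency form), the ratio-of-sums estimate, its
#' leave-one-out jackknife standard error, and the two-tailed z test.
#'
#' @slot quartet named character vector `(P1, P2, P3, O)`.
#' @slot mode `"counts"` or `"frequencies"`.
#' @slot d the D estimate, in `[-1, 1]`.
#' @slot se jackknife standard error (`NA` when fewer than 2 usable blocks).
#' @slot z `d / se`.
#' @slot p two-tailed normal p-value `2 * (1 - pnorm(|z|))`.
#' @slot nBlocks number of jackknife blocks used.
#' @slot numerator,denominator the ratio-of-sums components.
#' @slot flags character vector of quality flags (e.g. `"degenerate"`,
#'   `"untestable"`, `"undefined"`).
#' @exportClass DResult
setClass("DResult",
  representation(
    quartet = "character", mode = "character",
    d = "numeric", se = "numeric", z = "numeric", p = "numeric",
    nBlocks = "integer", numerator = "numeric", denominator = "numeric",
    flags = "character"
  )
)

setValidity("DResult", function(object) {
  msg <- character(0)
  if (length(object@quartet) != 4L)
    msg <- c(msg, "quartet must have 4 labels")
  if (!object@mode %in% c("counts", "frequencies"))
    msg <- c(msg, "mode must be 'counts' or 'frequencies'")
  if (is.finite(object@d) && abs(object@d) > 1 + 1e-12)
    msg <- c(msg, "|d| must be <= 1")
  if (is.finite(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn DResult-class compact display with significance stars.
#' @param object a `DResult`.
#' @export
setMethod("show", "DResult", function(object) {
  q <- object@quartet
  cat(sprintf("DResult: D(%s, %s, %s; %s) [%s mode]\n",
              q[1], q[2], q[3], q[4], object@mode))
  cat(sprintf("  D = %.4f  SE = %s  z = %s  p = %s %s\n",
              object@d,
              ifelse(is.na(object@se), "NA", sprintf("%.4f", object@se)),
              ifelse(is.na(object@z), "NA", sprintf("%.3f", object@z)),
              ifelse(is.na(object@p), "NA", format.pval(object@p, digits = 3)),
              significanceStars(object@p)))
  cat(sprintf("  blocks = %d  numerator = %.4f  denominator = %.4f\n",
              object@nBlocks, object@numerator, object@denominator))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(object)
})

#' @rdname accessors
#' @export
setGeneric("dValue", function(x) standardGeneric("dValue"))
#' @rdname accessors
#' @export
setGeneric("dSE", function(x) standardGeneric("dSE"))
#' @rdname accessors
#' @export
setGeneric("dZ", function(x) standardGeneric("dZ"))
#' @rdname accessors
#' @export
setGeneric("dPValue", function(x) standardGeneric("dPValue"))
#' @rdname accessors
#' @export
setGeneric("quartet", function(x) standardGeneric("quartet"))
#' @rdname accessors
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' Accessors
#'
#' Slot accessors for [DResult-class] and [SimulationConfig-class] objects.
#'
#' @param x a `DResult` or `SimulationConfig`.
#' @return the corresponding scalar or character vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("dValue", "DResult", function(x) x@d)
#' @rdname accessors
#' @export
setMethod("dSE", "DResult", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("dZ", "DResult", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("dPValue", "DResult", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("quartet", "DResult", function(x) x@quartet)
#' @rdname accessors
#' @export
setMethod("nBlocks", "DResult", function(x) x@nBlocks)

#' @rdname accessors
#' @export
setGeneric("introgressionGamma", function(x) standardGeneric("introgressionGamma"))
#' @rdname accessors
#' @export
setMethod("introgressionGamma", "SimulationConfig", function(x) x@gamma)
#' @rdname accessors
#' @export
setGeneric("tInternal", function(x) standardGeneric("tInternal"))
#' @rdname accessors
#' @export
setMethod("tInternal", "SimulationConfig", function(x) x@tInternal)

#' @describeIn SimulationConfig-class one-line summary of the study conditions.
#' @param object a `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  q <- exp(-object@tInternal) / 3
  g <- object@gamma * (1 - 3 * q)
  cat("SimulationConfig:", object@nLoci, "loci x", object@sitesPerLocus, "nt\n")
  cat("  taxa:", paste(object@taxa, collapse = ", "),
      "(outgroup:", paste0(object@taxa[8], ")"), "\n")
  cat("  quartet (P1,P2,P3,O):", paste(object@quartet, collapse = ", "), "\n")
  cat(sprintf("  gamma = %.3f, tInternal = %.3f => P(introgressed) = %.3f, P(each ILS class) = %.3f\n",
              object@gamma, object@tInternal, g, q))
  cat(sprintf("  expected D = %.4f\n", expectedD(object@gamma, object@tInternal)))
  cat(sprintf("  mutRate = %.3f, omegaSelected = %.1f, fracSelected = %.2f, seed = %d\n",
              object@mutRate, object@omegaSelected, object@fracSelected, object@seed))
  invisible(object)
})

#' Convert a DResult to a one-row data frame
#'
#' @param x a [DResult-class].
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return a one-row `data.frame` with columns P1, P2, P3, O, mode, nBlocks,
#'   numerator, denominator, D, SE, z, p, stars, flags.
#' @export
as.data.frame.DResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    P1 = x@quartet[1], P2 = x@quartet[2], P3 = x@quartet[3], O = x@quartet[4],
    mode = x@mode, nBlocks = x@nBlocks,
    numerator = x@numerator, denominator = x@denominator,
    D = x@d, SE = x@se, z = x@z, p = x@p,
    stars = significanceStars(x@p),
    flags = paste(x@flags, collapse = ";"),
    stringsAsFactors = FALSE, row.names = row.names
  )
}

# stars convention used in figures: * <0.05, ** <0.01, *** <0.001
significanceStars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
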