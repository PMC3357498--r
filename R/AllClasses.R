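#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' GenotypePanel: biallelic SNP genotypes with a marker map
#'
#' Container for a set of individuals genotyped on a shared, ordered
#' marker map. Genotypes are stored as allele-B dosages: 0 (homozygous
#' for allele A), 1 (heterozygous), 2 (homozygous for allele B) and
#' \code{NA} (missing). Allele A is, by convention, the first allele
#' observed for that marker in the source file; the labels themselves are
#' kept in the marker table. Missing genotypes are carried through
#' explicitly and are never imputed.
#'
#' @slot genotypes integer matrix, individuals x markers, entries in
#'   \{0, 1, 2, NA\}.
#' @slot markers \code{data.frame} with one row per marker and columns
#'   \code{id}, \code{chrom}, \code{pos} (1-based bp), \code{cM}
#'   (genetic position, may be NA), \code{alleleA}, \code{alleleB}.
#'   Markers are sorted by (chrom, pos) with strictly increasing
#'   positions within each chromosome.
#' @slot individuals \code{data.frame} with one row per individual and
#'   columns \code{id}, \code{role} ("case" or "control"), \code{family}
#'   (family/sib-pair grouping, may be NA).
#'
#' @seealso [readPanel()], [callROH()], [pairwiseHFTable()]
#' @export
setClass("GenotypePanel",
  representation(
    genotypes = "matrix",
    markers = "data.frame",
    individuals = "data.frame"
  )
)

setValidity("GenotypePanel", function(object) {
  g <- object@genotypes
  mk <- object@markers
  ind <- object@individuals
  msg <- character()
  need <- c("id", "chrom", "pos", "cM", "alleleA", "alleleB")
  if (!all(need %in% names(mk)))
    msg <- c(msg, paste("markers must have columns:", paste(need, collapse = ", ")))
  if (!all(c("id", "role", "family") %in% names(ind)))
    msg <- c(msg, "individuals must have columns: id, role, family")
  if (length(msg)) return(msg)
  if (nrow(g) != nrow(ind))
    msg <- c(msg, "nrow(genotypes) != number of individuals")
  if (ncol(g) != nrow(mk))
    msg <- c(msg, "ncol(genotypes) != number of markers")
  if (anyDuplicated(ind$id))
    msg <- c(msg, "duplicated individual ids")
  bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
  if (any(bad))
    msg <- c(msg, "genotype entries must be 0, 1, 2 or NA")
  if (nrow(mk)) {
    if (any(mk$pos < 0, na.rm = TRUE))
      msg <- c(msg, "marker positions must be >= 0")
    byc <- split(mk$pos, factor(mk$chrom, levels = unique(mk$chrom)))
    if (any(vapply(byc, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
    if (any(mk$alleleA == mk$alleleB, na.rm = TRUE))
      msg <- c(msg, "markers must be biallelic with distinct allele labels")
  }
  if (length(msg)) msg else TRUE
})

#' PairwiseHFTable: EM-estimated haplotype frequencies for adjacent marker pairs
#'
#' For every pair of adjacent markers on the same chromosome, the four
#' two-locus haplotype frequencies (AB, Ab, aB, ab, where A/a are the
#' alleles of the left marker and B/b of the right marker), the number of
#' pairwise-complete control individuals \code{v} used, and the
#' rare-haplotype surrogate frequency \code{K} for that sample size.
#' Precomputed log conditional/marginal lookup tables (with the K
#' substitution already folded in per cell) make whole-region Markov-chain
#' evaluation a vector lookup.
#'
#' @slot pairs \code{data.frame} with columns \code{chrom}, \code{i},
#'   \code{j} (global marker indices of the left/right marker),
#'   \code{pAB}, \code{pAb}, \code{paB}, \code{pab}, \code{v},
#'   \code{K}, \code{converged}.
#' @slot markerIds character, marker ids of the panel the table was
#'   estimated from (consistency check when scoring).
#' @slot logCond numeric matrix nPairs x 4: log conditional
#'   P(right allele | left allele) per cell (AB, Ab, aB, ab order), with
#'   zero-frequency cells replaced by the K rule.
#' @slot logMarg numeric matrix nPairs x 2: log marginal frequency of the
#'   left marker's alleles (A, a), zero replaced by K.
#' @export
setClass("PairwiseHFTable",
  representation(
    pairs = "data.frame",
    markerIds = "character",
    logCond = "matrix",
    logMarg = "matrix"
  )
)

setValidity("PairwiseHFTable", function(object) {
  p <- object@pairs
  msg <- character()
  need <- c("chrom", "i", "j", "pAB", "pAb", "paB", "pab", "v", "K", "converged")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  f <- as.matrix(p[, c("pAB", "pAb", "paB", "pab")])
  if (nrow(f) && (any(f < 0) || any(f > 1)))
    msg <- c(msg, "haplotype frequencies must lie in [0, 1]")
  if (nrow(f) && any(abs(rowSums(f) - 1) > 1e-9))
    msg <- c(msg, "each pair's four haplotype frequencies must sum to 1")
  if (nrow(object@logCond) != nrow(p) || nrow(object@logMarg) != nrow(p))
    msg <- c(msg, "lookup tables out of step with pairs")
  if (length(msg)) msg else TRUE
})

#' NullDistribution: Monte-Carlo null of best-region statistics
#'
#' Sorted vector of best-region statistics (on the -log10 HBC scale, so
#' larger means more extreme) obtained from control genomes, together
#' with the mode, the round count and the seed that produced it.
#'
#' @slot mode character, one of "single", "multi", "sibpair".
#' @slot stats numeric, sorted ascending, length = number of rounds.
#' @slot seed integer seed used.
#' @slot params list of run parameters (ROH thresholds, N, T, ...).
#' @export
setClass("NullDistribution",
  representation(
    mode = "character",
    stats = "numeric",
    seed = "integer",
    params = "list"
  )
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (!object@mode %in% c("single", "multi", "sibpair"))
    msg <- c(msg, "mode must be single, multi or sibpair")
  if (is.unsorted(object@stats))
    msg <- c(msg, "stats must be sorted ascending")
  if (length(msg)) msg else TRUE
})
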