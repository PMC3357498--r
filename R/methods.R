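# Accessors and show methods for the core classes.

#' @rdname GenotypePanel-class
#' @aliases genotypes,GenotypePanel-method
#' @export
setMethod("genotypes", "GenotypePanel", function(x) x@genotypes)

#' @rdname GenotypePanel-class
#' @export
setMethod("markers", "GenotypePanel", function(x) x@markers)

#' @rdname GenotypePanel-class
#' @export
setMethod("individuals", "GenotypePanel", function(x) x@individuals)

#' @rdname GenotypePanel-class
#' @export
setMethod("nMarkers", "GenotypePanel", function(x) nrow(x@markers))

#' @rdname GenotypePanel-class
#' @export
setMethod("nIndividuals", "GenotypePanel", function(x) nrow(x@individuals))

#' @rdname GenotypePanel-class
#' @param i,j,drop individual (row) and marker (column) subscripts
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@individuals))
  if (missing(j)) j <- seq_len(nrow(x@markers))
  if (is.character(i)) i <- match(i, x@individuals$id)
  newGenotypePanel(
    x@genotypes[i, j, drop = FALSE],
    x@markers[j, , drop = FALSE],
    x@individuals[i, , drop = FALSE]
  )
})

setMethod("show", "GenotypePanel", function(object) {
  mk <- object@markers
  ind <- object@individuals
  cat("GenotypePanel:", nrow(ind), "individuals x", nrow(mk), "markers\n")
  if (nrow(ind))
    cat("  roles:", paste(sprintf("%s=%d", names(table(ind$role)),
                                  table(ind$role)), collapse = ", "), "\n")
  if (nrow(mk))
    cat("  chromosomes:", paste(unique(mk$chrom), collapse = ", "), "\n")
  mr <- mean(is.na(object@genotypes))
  cat(sprintf("  missing rate: %.4f\n", mr))
})

#' @rdname PairwiseHFTable-class
#' @export
setMethod("hfPairs", "PairwiseHFTable", function(x) x@pairs)

setMethod("show", "PairwiseHFTable", function(object) {
  p <- object@pairs
  cat("PairwiseHFTable:", nrow(p), "adjacent marker pairs\n")
  if (nrow(p)) {
    cat(sprintf("  control sample size v: %d-%d individuals\n",
                min(p$v), max(p$v)))
    cat(sprintf("  pairs with an unseen haplotype (K substitution armed): %d\n",
                sum(p$pAB == 0 | p$pAb == 0 | p$paB == 0 | p$pab == 0)))
    if (!all(p$converged)) cat("  WARNING:", sum(!p$converged),
                               "pairs hit the EM iteration cap\n")
  }
})

#' @rdname NullDistribution-class
#' @export
setMethod("nullStats", "NullDistribution", function(x) x@stats)

#' @rdname NullDistribution-class
#' @export
setMethod("length", "NullDistribution", function(x) length(x@stats))

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution (mode = %s): %d rounds, seed %d\n",
              object@mode, length(object@stats), object@seed))
  if (length(object@stats))
    cat(sprintf("  -log10(HBC) quantiles: median %.2f, 95%% %.2f, max %.2f\n",
                stats::median(object@stats),
                stats::quantile(object@stats, 0.95), max(object@stats)))
})

# internal constructor used everywhere; validates once
newGenotypePanel <- function(genotypes, markers, individuals) {
  rownames(genotypes) <- individuals$id
  colnames(genotypes) <- markers$id
  rownames(markers) <- NULL
  rownames(individuals) <- NULL
  new("GenotypePanel", genotypes = genotypes, markers = markers,
      individuals = individuals)
}

#' Construct a GenotypePanel from components
#'
#' @param genotypes integer matrix (individuals x markers) of allele-B
#'   dosages in \{0, 1, 2, NA\}.
#' @param markers marker table (id, chrom, pos, cM, alleleA, alleleB);
#'   missing optional columns are filled with defaults.
#' @param individuals individual table (id, role, family) or a character
#'   vector of ids (all assigned role "control").
#' @return a validated \code{GenotypePanel} with markers sorted by
#'   (chrom, pos).
#' @examples
#' mk <- data.frame(id = c("s1", "s2"), chrom = "1", pos = c(100L, 200L))
#' gp <- GenotypePanel(matrix(c(0L, 2L, 1L, 0L), 2, 2), mk, c("a", "b"))
#' nMarkers(gp)
#' @export
GenotypePanel <- function(genotypes, markers, individuals) {
  genotypes <- matrix(as.integer(genotypes), nrow = nrow(genotypes))
  if (is.character(individuals))
    individuals <- data.frame(id = individuals, role = "control",
                              family = NA_character_)
  if (is.null(individuals$role)) individuals$role <- "control"
  if (is.null(individuals$family)) individuals$family <- NA_character_
  if (is.null(markers$cM)) markers$cM <- NA_real_
  if (is.null(markers$alleleA)) markers$alleleA <- "A"
  if (is.null(markers$alleleB)) markers$alleleB <- "B"
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  o <- order(factor(markers$chrom, levels = unique(markers$chrom)), markers$pos)
  newGenotypePanel(genotypes[, o, drop = FALSE],
                   markers[o, , drop = FALSE], individuals)
}
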