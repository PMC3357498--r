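# Runs of homozygosity: the candidate regions that the haplotype
# frequency statistic evaluates.

#' Call runs of homozygosity
#'
#' Scans each requested individual chromosome by chromosome for maximal
#' homozygous runs. A run may contain at most `maxHet` heterozygous and
#' `maxMissing` missing genotypes; its boundaries are always homozygous
#' markers (no half-marker extension). The scan is greedy left-to-right:
#' each run is extended rightwards until one more marker would exceed a
#' budget, so returned regions are non-overlapping within an individual.
#' Genotyping error is not modelled; the statistic presumes clean
#' homozygous tracts, so the heterozygote tolerance defaults to zero.
#'
#' @param panel a [GenotypePanel]
#' @param individuals ids (or indices) to scan; default all
#' @param minSnps minimum number of markers spanned (must be >= 2,
#'   because the Markov-chain frequency needs at least one marker pair)
#' @param maxHet maximum heterozygous genotypes tolerated inside a run
#' @param maxMissing maximum missing genotypes tolerated inside a run
#' @return a `GRanges` (1-based closed bp intervals) with metadata
#'   columns `individual`, `iFirst`, `iLast` (global marker indices),
#'   `nSnps`, `nHet`, `nMissing`, sorted by (individual, chrom, start)
#' @examples
#' gp <- generatePanel(populationModel(nMarkers = 300, seed = 2), 5)$panel
#' callROH(gp, minSnps = 10)
#' @export
callROH <- function(panel, individuals = NULL, minSnps = 25L,
                    maxHet = 0L, maxMissing = 2L) {
  if (minSnps < 2) stop("minSnps must be >= 2 (region frequency needs >= 2 markers)")
  ind <- individuals(panel)
  if (is.null(individuals)) individuals <- ind$id
  if (is.numeric(individuals)) individuals <- ind$id[individuals]
  miss <- setdiff(individuals, ind$id)
  if (length(miss)) stop("unknown individual(s): ", paste(miss, collapse = ", "))
  mk <- markers(panel)
  chromStarts <- chromOffsets(mk)
  g <- genotypes(panel)
  out <- vector("list", length(individuals))
  for (k in seq_along(individuals)) {
    row <- g[match(individuals[k], ind$id), ]
    runs <- lapply(seq_along(chromStarts$chrom), function(ci) {
      idx <- chromStarts$from[ci]:chromStarts$to[ci]
      r <- rohScan(row[idx], minSnps, maxHet, maxMissing)
      if (nrow(r)) r[, 1:2] <- r[, 1:2] + chromStarts$from[ci] - 1L
      r
    })
    runs <- do.call(rbind, runs)
    out[[k]] <- if (nrow(runs)) cbind(runs, indiv = k) else NULL
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(emptyRegionGRanges())
  GenomicRanges::GRanges(
    seqnames = mk$chrom[out[, 1]],
    ranges = IRanges::IRanges(start = mk$pos[out[, 1]], end = mk$pos[out[, 2]]),
    individual = individuals[out[, 5]],
    iFirst = out[, 1], iLast = out[, 2],
    nSnps = out[, 2] - out[, 1] + 1L,
    nHet = out[, 3], nMissing = out[, 4])
}

emptyRegionGRanges <- function() {
  GenomicRanges::GRanges(individual = character(), iFirst = integer(),
                         iLast = integer(), nSnps = integer(),
                         nHet = integer(), nMissing = integer())
}

# chromosome blocks of a sorted marker table
chromOffsets <- function(mk) {
  chrom <- unique(mk$chrom)
  from <- match(chrom, mk$chrom)
  to <- c(from[-1] - 1L, nrow(mk))
  list(chrom = chrom, from = from, to = to)
}

# Greedy maximal-run scan over one chromosome's genotype codes.
# Returns matrix cols: iFirst, iLast, nHet, nMissing (local indices).
# Fast path: with maxHet = 0 the runs are the het-free segments, and a
# segment whose missing count fits the budget is emitted wholesale.
rohScan <- function(codes, minSnps, maxHet, maxMissing) {
  if (maxHet == 0L) {
    het <- !is.na(codes) & codes == 1L
    if (!any(is.na(codes))) {
      r <- rle(!het)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok <- r$values & r$lengths >= minSnps
      res <- cbind(iFirst = starts[ok], iLast = ends[ok],
                   nHet = rep(0L, sum(ok)), nMissing = rep(0L, sum(ok)))
      return(res)
    }
  }
  n <- length(codes)
  hom <- !is.na(codes) & codes != 1L
  het <- !is.na(codes) & codes == 1L
  mis <- is.na(codes)
  res <- matrix(0L, 0L, 4L)
  i <- 1L
  while (i <= n) {
    if (!hom[i]) { i <- i + 1L; next }
    nh <- 0L; nm <- 0L
    j <- i
    lastHom <- i
    while (j < n) {
      nh2 <- nh + het[j + 1L]
      nm2 <- nm + mis[j + 1L]
      if (nh2 > maxHet || nm2 > maxMissing) break
      j <- j + 1L; nh <- nh2; nm <- nm2
      if (hom[j]) lastHom <- j
    }
    # trim trailing non-homozygous markers
    nh <- nh - sum(het[(lastHom + 1L):j][seq_len(max(0L, j - lastHom))])
    nm <- nm - sum(mis[(lastHom + 1L):j][seq_len(max(0L, j - lastHom))])
    if (lastHom - i + 1L >= minSnps)
      res <- rbind(res, c(i, lastHom, nh, nm))
    i <- j + 1L
  }
  colnames(res) <- c("iFirst", "iLast", "nHet", "nMissing")
  res
}
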