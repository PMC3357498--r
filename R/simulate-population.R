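# LD-structured synthetic control populations with known truth. Two
# generating processes share one interface:
#  * "markov": each haplotype is drawn from a first-order Markov chain
#    over the markers, so true pairwise and whole-region haplotype
#    frequencies have closed forms (the same model class as the region
#    statistic);
#  * "pool": haplotypes are copying mosaics over a finite founder pool
#    (donor switches follow a Poisson process on the genetic map), which
#    creates genuinely rare long haplotypes for testing the K correction
#    and realistic background runs of homozygosity. A switch scale of
#    Inf reduces to whole-haplotype resampling from the pool.

#' Define a synthetic population model
#'
#' Fixes, deterministically from `seed`, the marker map, per-marker
#' allele frequencies, adjacent-marker LD and (for the pool mode) the
#' founder haplotype pool and its frequencies. The genetic map is
#' uniform at 1 cM/Mb.
#'
#' @param nMarkers total number of markers
#' @param nChrom number of chromosomes (markers split evenly)
#' @param spacingBp distance between adjacent markers in bp
#' @param freqRange range of per-marker alternate-allele frequencies
#' @param rho target correlation between adjacent markers' alleles on a
#'   haplotype (clipped to the feasible range per pair)
#' @param mode `"pool"` or `"markov"`
#' @param poolSize number of founder haplotypes in the pool (pool mode)
#' @param switchScaleCM mean genetic distance between donor switches of
#'   the copying process, in cM; `Inf` = whole-haplotype resampling
#' @param poolWeights `"dirichlet"` (uneven haplotype frequencies,
#'   Dirichlet(1)) or `"uniform"`
#' @param seed integer seed fixing the model
#' @return a `populationModel` list (markers, frequencies, transition
#'   tables, pool haplotypes/weights)
#' @examples
#' m <- populationModel(nMarkers = 100, seed = 1)
#' p <- generatePanel(m, 20)
#' p$panel
#' @export
populationModel <- function(nMarkers = 5000L, nChrom = 2L,
                            spacingBp = 20000L, freqRange = c(0.05, 0.95),
                            rho = 0.7, mode = c("pool", "markov"),
                            poolSize = 200L, switchScaleCM = 5,
                            poolWeights = c("dirichlet", "uniform"),
                            seed = 1L) {
  mode <- match.arg(mode)
  poolWeights <- match.arg(poolWeights)
  perChrom <- rep(nMarkers %/% nChrom, nChrom)
  perChrom[seq_len(nMarkers %% nChrom)] <- perChrom[seq_len(nMarkers %% nChrom)] + 1L
  chrom <- rep(as.character(seq_len(nChrom)), perChrom)
  posWithin <- unlist(lapply(perChrom, function(k) seq_len(k))) * spacingBp
  mk <- data.frame(id = sprintf("snp%05d", seq_len(nMarkers)),
                   chrom = chrom, pos = as.integer(posWithin),
                   cM = posWithin / 1e6,      # 1 cM/Mb
                   alleleA = "A", alleleB = "B")
  set.seed(seed)
  pB <- stats::runif(nMarkers, freqRange[1], freqRange[2])
  # adjacent-pair joint P(prev = B, next = B), clipped inside Frechet
  # bounds so every two-locus haplotype keeps positive probability
  left <- pB[-nMarkers]; right <- pB[-1]
  p11 <- left * right + rho * sqrt(left * (1 - left) * right * (1 - right))
  loB <- pmax(0, left + right - 1) + 1e-4
  hiB <- pmin(left, right) - 1e-4
  p11 <- pmin(pmax(p11, loB), hiB)
  sameChrom <- chrom[-nMarkers] == chrom[-1]
  p11[!sameChrom] <- NA
  model <- list(markers = mk, pB = pB, p11 = p11, rho = rho, mode = mode,
                seed = seed, spacingBp = spacingBp,
                switchScaleCM = switchScaleCM)
  class(model) <- "populationModel"
  if (mode == "pool") {
    model$pool <- drawChainHaplotypes(model, poolSize)
    w <- if (poolWeights == "dirichlet") stats::rexp(poolSize) else
      rep(1, poolSize)
    model$poolW <- w / sum(w)
  }
  model
}

#' @export
print.populationModel <- function(x, ...) {
  cat(sprintf("populationModel (%s): %d markers on %d chromosome(s), seed %d\n",
              x$mode, nrow(x$markers), length(unique(x$markers$chrom)),
              x$seed))
  if (x$mode == "pool")
    cat(sprintf("  pool: %d founder haplotypes, switch scale %s cM\n",
                nrow(x$pool), format(x$switchScaleCM)))
  invisible(x)
}

# n haplotypes from the first-order chain (rows: haplotypes, 0/1 dosage)
drawChainHaplotypes <- function(model, n) {
  mk <- model$markers
  m <- nrow(mk)
  h <- matrix(0L, n, m)
  co <- chromOffsets(mk)
  for (ci in seq_along(co$chrom)) {
    idx <- co$from[ci]:co$to[ci]
    h[, idx[1]] <- stats::rbinom(n, 1L, model$pB[idx[1]])
    for (j in idx[-1]) {
      prev <- h[, j - 1L]
      p11 <- model$p11[j - 1L]
      pBgivenB <- p11 / model$pB[j - 1L]
      pBgivenA <- (model$pB[j] - p11) / (1 - model$pB[j - 1L])
      pr <- ifelse(prev == 1L, pBgivenB, pBgivenA)
      h[, j] <- stats::rbinom(n, 1L, pr)
    }
  }
  h
}

# one mosaic haplotype over the pool; returns list(hap, path) where path
# is a data.frame (from, to, donor) in marker indices
drawMosaicHaplotype <- function(model) {
  mk <- model$markers
  co <- chromOffsets(mk)
  hap <- integer(nrow(mk))
  path <- list()
  for (ci in seq_along(co$chrom)) {
    idx <- co$from[ci]:co$to[ci]
    cm <- mk$cM[idx]
    len <- cm[length(cm)] - cm[1]
    nSwitch <- if (is.finite(model$switchScaleCM))
      stats::rpois(1, len / model$switchScaleCM) else 0L
    cuts <- sort(stats::runif(nSwitch, cm[1], cm[1] + len))
    donors <- sample.int(nrow(model$pool), nSwitch + 1L, replace = TRUE,
                         prob = model$poolW)
    seg <- findInterval(cm, cuts) + 1L
    hap[idx] <- model$pool[cbind(donors[seg], idx)]
    path[[ci]] <- data.frame(
      from = idx[c(1L, which(diff(seg) > 0) + 1L)],
      to = idx[c(which(diff(seg) > 0), length(idx))],
      donor = donors[unique(seg)])
  }
  list(hap = hap, path = do.call(rbind, path))
}

#' Generate a genotype panel from a population model
#'
#' Draws `2 * nIndividuals` haplotypes from the model's generating
#' process, pairs them into diploid genotypes and returns both the
#' unphased [GenotypePanel] and the phased truth. Optionally introduces
#' missing genotypes completely at random.
#'
#' @param model a [populationModel()]
#' @param nIndividuals number of diploid individuals
#' @param seed optional seed for this draw (the model itself is already
#'   fixed); the result is bit-reproducible given (model, seed)
#' @param role role label for the individuals ("control" or "case")
#' @param idPrefix prefix of individual ids
#' @param missingRate per-genotype missingness probability
#' @return list with `panel` (a [GenotypePanel]), `haplotypes`
#'   (2n x markers 0/1 matrix, rows 2i-1 and 2i belong to individual i)
#'   and, in pool mode, `paths` (donor mosaic of every haplotype)
#' @export
generatePanel <- function(model, nIndividuals, seed = NULL,
                          role = "control", idPrefix = role,
                          missingRate = 0) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(model$markers)
  nh <- 2L * nIndividuals
  paths <- NULL
  if (model$mode == "markov") {
    haps <- drawChainHaplotypes(model, nh)
  } else {
    draws <- lapply(seq_len(nh), function(i) drawMosaicHaplotype(model))
    haps <- do.call(rbind, lapply(draws, `[[`, "hap"))
    paths <- lapply(draws, `[[`, "path")
  }
  g <- haps[seq(1, nh, 2), , drop = FALSE] + haps[seq(2, nh, 2), , drop = FALSE]
  if (missingRate > 0)
    g[stats::runif(length(g)) < missingRate] <- NA_integer_
  ind <- data.frame(id = sprintf("%s%04d", idPrefix, seq_len(nIndividuals)),
                    role = role, family = NA_character_)
  list(panel = GenotypePanel(g, model$markers, ind),
       haplotypes = haps, paths = paths)
}

#' Closed-form pairwise haplotype frequency table of a model
#'
#' The exact adjacent-pair haplotype frequencies implied by the
#' generating process: the chain's joint law in markov mode; in pool
#' mode, a mixture of the pool's within-donor joint frequencies and the
#' product of marginals, weighted by the probability that no donor
#' switch falls between the two markers. The nominal control sample
#' size is set very large so the K surrogate is effectively zero.
#'
#' @param model a [populationModel()]
#' @param v nominal sample size recorded in the table
#' @return a [PairwiseHFTable]
#' @export
trueHFTable <- function(model, v = 1e9) {
  mk <- model$markers
  m <- nrow(mk)
  sameChrom <- which(mk$chrom[-m] == mk$chrom[-1])
  li <- sameChrom; ri <- li + 1L
  if (model$mode == "markov") {
    p11 <- model$p11[li]
    pL <- model$pB[li]; pR <- model$pB[ri]
  } else {
    w <- model$poolW
    pL <- as.numeric(crossprod(w, model$pool[, li, drop = FALSE]))
    pR <- as.numeric(crossprod(w, model$pool[, ri, drop = FALSE]))
    within <- as.numeric(crossprod(w, model$pool[, li, drop = FALSE] *
                                        model$pool[, ri, drop = FALSE]))
    stay <- if (is.finite(model$switchScaleCM))
      exp(-(mk$cM[ri] - mk$cM[li]) / model$switchScaleCM) else 1
    p11 <- stay * within + (1 - stay) * pL * pR
  }
  # cell order pAB..pab with A/a = ref/alt of left marker, B/b of right
  pairs <- data.frame(chrom = mk$chrom[li], i = li, j = ri,
                      pAB = 1 - pL - pR + p11, pAb = pR - p11,
                      paB = pL - p11, pab = p11,
                      v = v, K = rareHaplotypeK(v), converged = TRUE)
  buildHFTable(pairs, mk$id)
}
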