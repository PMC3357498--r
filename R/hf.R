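# Core statistic: EM estimation of two-locus haplotype frequencies from
# unphased control genotypes, the rare-haplotype surrogate frequency K,
# and the first-order Markov-chain evaluation of the population frequency
# HF of an entire homozygous region. HBC_s = HF^2.

# ---- two-locus EM ---------------------------------------------------------

# 9-class genotype counts for a set of marker pairs.
# g: dosage matrix; li, ri: vectors of left/right marker columns.
# Returns list(counts = nPairs x 9 matrix (class = 3*gl + gr + 1), v)
pairClassCounts <- function(g, li, ri) {
  np <- length(li)
  counts <- matrix(0, np, 9)
  gl <- g[, li, drop = FALSE]
  gr <- g[, ri, drop = FALSE]
  ok <- !is.na(gl) & !is.na(gr)
  for (a in 0:2) for (b in 0:2) {
    counts[, 3 * a + b + 1] <- colSums(ok & gl == a & gr == b, na.rm = TRUE)
  }
  list(counts = counts, v = rowSums(counts))
}

# per-individual contribution to pairClassCounts (for leave-one-out)
pairClassOfIndividual <- function(g, li, ri, row) {
  gl <- g[row, li]
  gr <- g[row, ri]
  cls <- 3L * gl + gr + 1L
  cls[is.na(gl) | is.na(gr)] <- NA_integer_
  cls
}

# Vectorized EM over pairs given 9-class counts. Only the double
# heterozygote class is phase-ambiguous; all other classes contribute
# known haplotypes. Deterministic: initialized at linkage equilibrium
# (or at `init` when warm-starting).
emFromCounts <- function(counts, tol = 1e-8, maxIter = 1000L, init = NULL) {
  n <- function(a, b) counts[, 3 * a + b + 1]
  kAB <- 2 * n(0, 0) + n(0, 1) + n(1, 0)
  kAb <- n(0, 1) + 2 * n(0, 2) + n(1, 2)
  kaB <- n(1, 0) + 2 * n(2, 0) + n(2, 1)
  kab <- n(1, 2) + n(2, 1) + 2 * n(2, 2)
  d <- n(1, 1)
  v <- rowSums(counts)
  tot <- 2 * v
  if (any(v == 0))
    stop("pair(s) with zero informative individuals: ",
         paste(utils::head(which(v == 0), 5), collapse = ", "))
  if (is.null(init)) {
    pA <- (kAB + kAb + d) / tot
    pB <- (kAB + kaB + d) / tot
    p <- cbind(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  } else {
    p <- init
  }
  iter <- 0L
  active <- rep(TRUE, nrow(counts))
  repeat {
    iter <- iter + 1L
    den <- p[active, 1] * p[active, 4] + p[active, 2] * p[active, 3]
    w <- ifelse(den > 0, p[active, 1] * p[active, 4] / den, 0.5)
    wd <- w * d[active]
    pNew <- cbind(kAB[active] + wd, kAb[active] + d[active] - wd,
                  kaB[active] + d[active] - wd, kab[active] + wd) / tot[active]
    delta <- apply(abs(pNew - p[active, , drop = FALSE]), 1, max)
    p[active, ] <- pNew
    active[active] <- delta >= tol
    if (!any(active) || iter >= maxIter) break
  }
  list(p = p, v = v, converged = !active, iterations = iter)
}

#' EM estimate of two-locus haplotype frequencies
#'
#' Maximum-likelihood estimate of the four haplotype frequencies
#' (AB, Ab, aB, ab) of a marker pair from unphased genotypes, by EM.
#' Only double heterozygotes carry phase ambiguity; the E step splits
#' them between the cis (AB/ab) and trans (Ab/aB) configurations in
#' proportion to the current frequency products. Initialization is at
#' linkage equilibrium and the procedure is deterministic.
#'
#' @param controls a [GenotypePanel] of population controls
#' @param i,j marker indices (or ids) of the pair
#' @param tol convergence threshold on the largest absolute frequency
#'   change per iteration
#' @param maxIter iteration cap; non-convergence returns the last
#'   iterate with a warning
#' @return list with `p` (named frequencies AB, Ab, aB, ab), `v`
#'   (pairwise-complete control count) and `converged`
#' @examples
#' gp <- generatePanel(populationModel(nMarkers = 10, seed = 3), 50)$panel
#' emPairwiseHF(gp, 1, 2)
#' @export
emPairwiseHF <- function(controls, i, j, tol = 1e-8, maxIter = 1000L) {
  mk <- markers(controls)
  if (is.character(i)) i <- match(i, mk$id)
  if (is.character(j)) j <- match(j, mk$id)
  cc <- pairClassCounts(genotypes(controls), i, j)
  if (cc$v == 0) stop("no control is genotyped at both markers")
  fit <- emFromCounts(cc$counts, tol = tol, maxIter = maxIter)
  if (!fit$converged)
    warning("EM did not converge within ", maxIter, " iterations")
  list(p = stats::setNames(as.numeric(fit$p), c("AB", "Ab", "aB", "ab")),
       v = as.integer(fit$v), converged = fit$converged)
}

# ---- rare-haplotype correction -------------------------------------------

#' Surrogate frequency for a haplotype unseen in controls
#'
#' A haplotype observed in a patient but absent from the controls is
#' assigned the frequency K at which it would escape observation in the
#' control sample with 95% probability: K solves
#' \eqn{(1-K)^{2v} = 0.95} for v diploid controls (2v haplotypes).
#' The haplotype count per control is configurable because the source
#' description ("sample size (v)") is ambiguous between haplotypes and
#' individuals; the default reads v as diploid individuals.
#'
#' @param v control sample size, in individuals
#' @param confidence non-observation probability defining K (0.95)
#' @param nHaplotypes number of control haplotypes; default `2 * v`
#' @return the frequency K
#' @examples
#' rareHaplotypeK(1)    # 1 - 0.95^(1/2)
#' rareHaplotypeK(112)  # control count of a HapMap CEPH non-founder set
#' @export
rareHaplotypeK <- function(v, confidence = 0.95, nHaplotypes = 2 * v) {
  if (any(v <= 0)) stop("v must be a positive number of individuals")
  1 - confidence^(1 / nHaplotypes)
}

# ---- pairwise HF table ----------------------------------------------------

#' Estimate the adjacent-pair haplotype frequency table from controls
#'
#' Runs the two-locus EM on every pair of adjacent markers within each
#' chromosome and assembles a [PairwiseHFTable], including the
#' per-pair sample size v (pairwise-complete individuals), the
#' rare-haplotype surrogate K(v), and precomputed log conditional /
#' marginal lookup tables used by [scoreRegions()]. The K substitution
#' is folded into the lookup per cell: a cell with estimated frequency
#' zero is replaced by K and the remaining three frequencies of the pair
#' are rescaled by (1-K), so that a queried zero-frequency transition
#' evaluates to K / (K + (1-K) * rowRest) while non-zero cells are
#' untouched.
#'
#' @param controls a [GenotypePanel]; all individuals in it are used
#' @param tol,maxIter EM convergence parameters, see [emPairwiseHF()]
#' @param exclude ids of individuals to drop before estimation
#'   (leave-one-out scoring)
#' @param warmStart optional [PairwiseHFTable] whose frequencies seed
#'   the EM (used internally for fast leave-one-out refits)
#' @return a [PairwiseHFTable]
#' @export
pairwiseHFTable <- function(controls, tol = 1e-8, maxIter = 1000L,
                            exclude = NULL, warmStart = NULL) {
  mk <- markers(controls)
  g <- genotypes(controls)
  if (!is.null(exclude)) {
    keep <- !(individuals(controls)$id %in% exclude)
    g <- g[keep, , drop = FALSE]
  }
  co <- chromOffsets(mk)
  li <- unlist(lapply(seq_along(co$chrom), function(ci) {
    if (co$to[ci] > co$from[ci]) co$from[ci]:(co$to[ci] - 1L) else integer()
  }))
  if (!length(li)) stop("need at least 2 markers on some chromosome")
  ri <- li + 1L
  cc <- pairClassCounts(g, li, ri)
  init <- if (!is.null(warmStart))
    as.matrix(warmStart@pairs[, c("pAB", "pAb", "paB", "pab")]) else NULL
  fit <- emFromCounts(cc$counts, tol = tol, maxIter = maxIter, init = init)
  if (!all(fit$converged))
    warning(sum(!fit$converged), " pair(s) did not converge in ",
            maxIter, " EM iterations; last iterate kept")
  pairs <- data.frame(chrom = mk$chrom[li], i = li, j = ri,
                      pAB = fit$p[, 1], pAb = fit$p[, 2],
                      paB = fit$p[, 3], pab = fit$p[, 4],
                      v = as.integer(fit$v),
                      K = rareHaplotypeK(fit$v),
                      converged = fit$converged)
  buildHFTable(pairs, mk$id)
}

# assemble lookup tables; shared by pairwiseHFTable and readHFTable
buildHFTable <- function(pairs, markerIds) {
  J <- as.matrix(pairs[, c("pAB", "pAb", "paB", "pab")])
  K <- pairs$K
  rowA <- J[, 1] + J[, 2]
  rowa <- J[, 3] + J[, 4]
  cond <- J
  rs <- cbind(rowA, rowA, rowa, rowa)
  other <- J[, c(2, 1, 4, 3)]
  pos <- J > 0
  cond[pos] <- (J / rs)[pos]
  Km <- matrix(K, nrow(J), 4)
  cond[!pos] <- (Km / (Km + (1 - Km) * other))[!pos]
  marg <- cbind(ifelse(rowA > 0, rowA, K), ifelse(rowa > 0, rowa, K))
  new("PairwiseHFTable", pairs = pairs, markerIds = as.character(markerIds),
      logCond = log(cond), logMarg = log(marg))
}

#' Serialize / read a pairwise HF table
#'
#' TSV cache of the EM results (marker_i, marker_j, P_AB, P_Ab, P_aB,
#' P_ab, v) so repeated runs against the same control panel skip
#' re-estimation. Reading requires the panel to re-anchor marker ids.
#'
#' @param table a [PairwiseHFTable]
#' @param file TSV path
#' @param panel the [GenotypePanel] the table belongs to
#' @return `writeHFTable` the path, invisibly; `readHFTable` a
#'   [PairwiseHFTable]
#' @export
writeHFTable <- function(table, file) {
  p <- table@pairs
  df <- data.frame(marker_i = table@markerIds[p$i],
                   marker_j = table@markerIds[p$j],
                   P_AB = p$pAB, P_Ab = p$pAb, P_aB = p$paB, P_ab = p$pab,
                   v = p$v, converged = p$converged)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeHFTable
#' @export
readHFTable <- function(file, panel) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c(marker_i = "character",
                                         marker_j = "character"))
  mk <- markers(panel)
  i <- match(df$marker_i, mk$id)
  j <- match(df$marker_j, mk$id)
  if (anyNA(i) || anyNA(j))
    stop("cached table refers to markers absent from the panel")
  pairs <- data.frame(chrom = mk$chrom[i], i = i, j = j,
                      pAB = df$P_AB, pAb = df$P_Ab, paB = df$P_aB,
                      pab = df$P_ab, v = df$v,
                      K = rareHaplotypeK(df$v), converged = df$converged)
  buildHFTable(pairs, mk$id)
}

# ---- Markov-chain region frequency ---------------------------------------

#' Evaluate the haplotype frequency of homozygous regions
#'
#' Computes, for each region, the population frequency HF of the entire
#' homozygous haplotype under a first-order Markov chain over the
#' adjacent-pair haplotype frequencies:
#' \deqn{HF = P(g_1) \prod_{i=2}^{n} P(g_{i-1}, g_i) / P(g_{i-1})}
#' where \eqn{g_i} is the homozygous allele at the i-th marker of the
#' region. All products are accumulated in log space; underflow of the
#' linear-scale HF for long regions is expected and harmless. A queried
#' transition with estimated frequency zero is replaced by the
#' rare-haplotype surrogate K of that pair (see [pairwiseHFTable()]).
#' Heterozygous exceptions and missing genotypes inside a region are
#' bridged by marginalizing the chain over the unobserved allele
#' (product of the raw conditional matrices across the gap).
#'
#' The probability of the region being homozygous by chance in a single
#' patient is \eqn{HBC_s = HF^2}.
#'
#' @param regions `GRanges` from [callROH()] (metadata columns
#'   `individual`, `iFirst`, `iLast`)
#' @param panel the [GenotypePanel] holding the individuals' genotypes
#' @param table a [PairwiseHFTable] estimated from controls on the same
#'   marker map
#' @return `regions` with metadata columns `logHF` (natural log),
#'   `hf`, `hbcS` (= hf^2; 0 on underflow) and `score`
#'   (\eqn{-\log_{10} HBC_s}, the statistic used for empirical
#'   P-values)
#' @examples
#' pop <- generatePanel(populationModel(nMarkers = 400, seed = 4), 60)
#' tab <- pairwiseHFTable(pop$panel)
#' r <- callROH(pop$panel, minSnps = 10)
#' scoreRegions(r, pop$panel, tab)
#' @export
scoreRegions <- function(regions, panel, table) {
  mk <- markers(panel)
  if (!identical(table@markerIds, as.character(mk$id)))
    stop("HF table and panel marker maps disagree; harmonize panels first")
  np <- nrow(table@pairs)
  pairAt <- integer(nrow(mk))        # pair row whose left marker is i
  pairAt[table@pairs$i] <- seq_len(np)
  g <- genotypes(panel)
  ids <- individuals(panel)$id
  n <- length(regions)
  logHF <- numeric(n)
  mc <- S4Vectors::mcols(regions)
  for (r in seq_len(n)) {
    row <- match(mc$individual[r], ids)
    span <- mc$iFirst[r]:mc$iLast[r]
    codes <- g[row, span]
    logHF[r] <- chainLogHF(codes, span, table, pairAt)
  }
  mc$logHF <- logHF
  mc$hf <- exp(logHF)
  mc$hbcS <- mc$hf^2
  mc$score <- -2 * logHF / log(10)
  S4Vectors::mcols(regions) <- mc
  regions
}

# log HF of one region; codes are dosages over global marker span.
chainLogHF <- function(codes, span, table, pairAt) {
  hom <- which(!is.na(codes) & codes != 1L)
  if (length(hom) < 2) stop("region frequency needs >= 2 homozygous markers")
  al <- 1L + (codes[hom] == 2L)           # 1 = allele A, 2 = allele B side
  gi <- span[hom]                          # global indices of hom markers
  p1 <- pairAt[gi[1]]
  if (p1 == 0) p1 <- pairAt[gi[1] - 1L]    # last marker of chromosome
  acc <- table@logMarg[p1, al[1]]
  gaps <- which(diff(gi) > 1L)
  # contiguous steps: direct lookup of the K-adjusted conditionals
  step <- which(diff(gi) == 1L)
  if (length(step)) {
    cell <- (al[step] - 1L) * 2L + al[step + 1L]
    acc <- acc + sum(table@logCond[cbind(pairAt[gi[step]], cell)])
  }
  # bridged steps: marginalize raw conditionals across the gap
  for (s in gaps) {
    M <- diag(2)
    for (m in gi[s]:(gi[s + 1L] - 1L)) {
      pr <- pairAt[m]
      J <- matrix(as.numeric(table@pairs[pr, c("pAB", "pAb", "paB", "pab")]),
                  2, 2, byrow = TRUE)
      rs <- rowSums(J)
      Craw <- J / ifelse(rs > 0, rs, 1)[row(J)]
      M <- M %*% Craw
    }
    q <- M[al[s], al[s + 1L]]
    if (q == 0) q <- table@pairs$K[pairAt[gi[s + 1L] - 1L]]
    acc <- acc + log(q)
  }
  acc
}

# fast variant used by the Monte-Carlo machinery: scores many regions of
# one individual given precomputed per-marker transition logs
precomputeIndividualChain <- function(codes, table, pairAt) {
  al <- ifelse(is.na(codes) | codes == 1L, NA_integer_, 1L + (codes == 2L))
  n <- length(al)
  trans <- rep(NA_real_, n)          # trans[m]: log step from m-1 to m
  ok <- which(!is.na(al[-n]) & !is.na(al[-1]) & pairAt[seq_len(n - 1)] > 0)
  cell <- (al[ok] - 1L) * 2L + al[ok + 1L]
  trans[ok + 1L] <- table@logCond[cbind(pairAt[ok], cell)]
  list(al = al, trans = trans)
}
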