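# Shared fixtures and independent oracles, all built in code.

# a tiny panel from an explicit dosage matrix (one chromosome)
tinyPanel <- function(g, chrom = "1", ids = NULL, role = "control") {
  g <- matrix(as.integer(g), nrow = nrow(g))
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(nrow(g)))
  mk <- data.frame(id = sprintf("m%03d", seq_len(ncol(g))),
                   chrom = chrom, pos = seq_len(ncol(g)) * 1000L,
                   cM = seq_len(ncol(g)) * 0.001,
                   alleleA = "A", alleleB = "C")
  GenotypePanel(g, mk, data.frame(id = ids, role = role,
                                  family = NA_character_))
}

# hand-written .ped/.map files: 3 individuals x 4 markers
writeTinyPed <- function(dir = tempfile()) {
  dir.create(dir)
  writeLines(c("1\trs1\t0\t101", "1\trs2\t0\t202",
               "1\trs3\t0\t303", "2\trs4\t0\t55"),
             file.path(dir, "toy.map"))
  writeLines(c("f1 a 0 0 1 2 A A A C C C G G",
               "f2 b 0 0 2 1 A G A A C T G G",
               "0 c 0 0 1 1 G G C C 0 0 G T"),
             file.path(dir, "toy.ped"))
  file.path(dir, "toy")
}

# vectorized multinomial log-likelihood of two-locus genotype class
# counts at many haplotype-frequency points (pAB, pAb, paB, pab columns)
twoLocusLogLik <- function(counts, p) {
  P <- cbind(p[, 1]^2, 2 * p[, 1] * p[, 2], p[, 2]^2,
             2 * p[, 1] * p[, 3],
             2 * p[, 1] * p[, 4] + 2 * p[, 2] * p[, 3],
             2 * p[, 2] * p[, 4],
             p[, 3]^2, 2 * p[, 3] * p[, 4], p[, 4]^2)
  lp <- log(P)
  lp[P <= 0] <- -Inf
  lp[, counts == 0] <- 0
  as.numeric(lp %*% counts)
}

# brute-force maximization of the two-locus likelihood over the
# 3-simplex by iterative grid refinement (independent of the EM)
gridMaxTwoLocus <- function(counts, levels = 10L, res = 16L) {
  lo <- c(0, 0, 0); hi <- c(1, 1, 1)     # (pAB, pAb, paB); pab = 1 - sum
  best <- NULL
  for (lv in seq_len(levels)) {
    gr <- as.matrix(expand.grid(seq(lo[1], hi[1], length.out = res + 1),
                                seq(lo[2], hi[2], length.out = res + 1),
                                seq(lo[3], hi[3], length.out = res + 1)))
    gr <- cbind(gr, 1 - rowSums(gr))
    gr <- gr[gr[, 4] >= 0, , drop = FALSE]
    ll <- twoLocusLogLik(counts, gr)
    best <- as.numeric(gr[which.max(ll), ])
    step <- (hi - lo) / res
    lo <- pmax(best[1:3] - 2 * step, 0)
    hi <- pmin(best[1:3] + 2 * step, 1)
  }
  best
}

# 9-class counts from a dosage matrix for a marker pair
classCounts <- function(g, i, j) {
  out <- numeric(9)
  for (a in 0:2) for (b in 0:2)
    out[3 * a + b + 1] <- sum(g[, i] == a & g[, j] == b, na.rm = TRUE)
  out
}

# chain evaluation of a region's haplotype frequency from a phased
# haplotype matrix (direct counting; independent of the package chain)
countedChainHF <- function(haps, alleles, span) {
  n1 <- mean(haps[, span[1]] == alleles[1])
  acc <- log(n1)
  for (k in 2:length(span)) {
    i <- span[k - 1]; j <- span[k]
    joint <- mean(haps[, i] == alleles[k - 1] & haps[, j] == alleles[k])
    marg <- mean(haps[, i] == alleles[k - 1])
    acc <- acc + log(joint) - log(marg)
  }
  exp(acc)
}

# enumeration oracle for the N-of-T sharing probability: walk all 2^T
# carrier patterns, weight each by p^k (1-p)^(T-k), sum those with at
# least N carriers (no pbinom, no choose)
enumSharingTail <- function(p, N, T) {
  if (N <= 0) return(1)
  tot <- 0
  for (pat in 0:(2^T - 1)) {
    k <- sum(bitwAnd(bitwShiftR(pat, 0:(T - 1)), 1L))
    if (k >= N) tot <- tot + p^k * (1 - p)^(T - k)
  }
  tot
}

# the frozen default study population used by the heavier checks;
# cached per test run
studyModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- populationModel(seed = 42)
    cache
  }
})
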