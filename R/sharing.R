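# Statistics for homozygous regions shared by several patients and by
# affected sib pairs.

#' Find regions of shared homozygosity across individuals
#'
#' Identifies maximal region/carrier-set combinations over which at
#' least `minCarriers` individuals (i) are each inside one of their
#' runs of homozygosity and (ii) are homozygous for the same allele at
#' every marker of the interval. Heterozygous exceptions and missing
#' genotypes inside a run act as wildcards; a single interior marker at
#' which two carriers are homozygous for different alleles splits their
#' shared interval there.
#'
#' The search works like maximal perfect-haplotype-block discovery: per
#' chromosome, markers are partitioned into blocks within which the
#' identity grouping of run-covered individuals is constant; carrier
#' sets are then propagated across blocks, refined by intersection with
#' each block's identity groups, and emitted when they can be extended
#' in neither direction. A returned region is never contained in
#' another region with a superset of its carriers.
#'
#' @param regions `GRanges` of per-individual runs from [callROH()]
#' @param panel the [GenotypePanel] (used for the allele vectors)
#' @param minCarriers minimum number of sharing individuals; 1 returns
#'   the per-individual regions themselves
#' @param minSnps smallest reported interval, in markers; region
#'   frequencies need at least 2
#' @return `GRanges` with metadata columns `carriers` (CharacterList),
#'   `N` (carrier count), `iFirst`, `iLast`, `nSnps`
#' @export
findSharedRegions <- function(regions, panel, minCarriers = 2L,
                              minSnps = 2L) {
  mk <- markers(panel)
  g <- genotypes(panel)
  ids <- individuals(panel)$id
  mc <- S4Vectors::mcols(regions)
  out <- list()
  for (ch in unique(as.character(GenomicRanges::seqnames(regions)))) {
    sel <- as.character(GenomicRanges::seqnames(regions)) == ch
    iF <- mc$iFirst[sel]; iL <- mc$iLast[sel]
    who <- unique(mc$individual[sel])
    rows <- match(who, ids)
    lo <- min(iF); hi <- max(iL)
    span <- lo:hi
    nm <- length(span)
    ni <- length(who)
    cov <- matrix(FALSE, ni, nm)
    for (r in which(sel)) {
      w <- match(mc$individual[r], who)
      cov[w, (mc$iFirst[r]:mc$iLast[r]) - lo + 1L] <- TRUE
    }
    # per-marker state: 0/2 homozygous code, 3 = wildcard (het/missing)
    st <- g[rows, span, drop = FALSE]
    st[is.na(st) | st == 1L] <- 3L
    st[!cov] <- -1L                         # not covered
    # canonical per-marker partition key; block boundaries where the
    # coverage or identity grouping changes
    key <- apply(st, 2, paste, collapse = ".")
    newBlock <- c(TRUE, key[-1] != key[-nm])
    bFrom <- which(newBlock)
    bTo <- c(bFrom[-1] - 1L, nm)
    nb <- length(bFrom)
    groupsAt <- vector("list", nb)
    for (b in seq_len(nb)) {
      s <- st[, bFrom[b]]
      wc <- which(s == 3L)
      gl <- list()
      for (code in c(0L, 2L)) {
        mem <- which(s == code)
        if (length(mem)) gl[[length(gl) + 1L]] <- sort(c(mem, wc))
      }
      if (!length(gl) && length(wc)) gl[[1L]] <- wc
      groupsAt[[b]] <- gl
    }
    inGroup <- function(S, b) {
      if (b < 1L || b > nb) return(FALSE)
      any(vapply(groupsAt[[b]], function(G) all(S %in% G), logical(1)))
    }
    emit <- function(S, bStart, bEnd) {
      if (span[bTo[bEnd]] - span[bFrom[bStart]] + 1L < minSnps) return()
      out[[length(out) + 1L]] <<- list(
        chrom = ch, iFirst = span[bFrom[bStart]], iLast = span[bTo[bEnd]],
        carriers = sort(who[S]))
    }
    # carrier sets alive through the previous block, with their
    # (left-maximal) starting blocks
    carry <- list()
    for (b in seq_len(nb)) {
      nxt <- list()
      keys <- character()
      add <- function(S, start) {
        k <- paste(S, collapse = ",")
        if (k %in% keys) {
          # keep the earliest start for a set reachable two ways
          for (q in seq_along(nxt)) if (identical(nxt[[q]]$S, S))
            nxt[[q]]$start <<- min(nxt[[q]]$start, start)
        } else {
          keys <<- c(keys, k)
          nxt[[length(nxt) + 1L]] <<- list(S = S, start = start)
        }
      }
      # refine every live set against this block's identity groups (a
      # set wholly inside a group survives unchanged; a dying set still
      # spawns its surviving subsets)
      for (a in carry) {
        for (G in groupsAt[[b]]) {
          S2 <- intersect(a$S, G)
          if (length(S2) >= minCarriers) add(S2, a$start)
        }
      }
      # fresh seeds: this block's own groups, if left-maximal here
      for (G in groupsAt[[b]]) {
        if (length(G) >= minCarriers && !inGroup(G, b - 1L)) add(G, b)
      }
      # sets that could not continue into block b end at block b - 1
      for (a in carry) if (!inGroup(a$S, b)) emit(a$S, a$start, b - 1L)
      carry <- nxt
    }
    for (a in carry) emit(a$S, a$start, nb)
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges(carriers = S4Vectors::SimpleList(),
                                  N = integer(), iFirst = integer(),
                                  iLast = integer(), nSnps = integer()))
  }
  # drop regions dominated by another (interval and carriers subsets)
  n <- length(out)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !keep[i] || !keep[j]) next
    if (out[[j]]$chrom == out[[i]]$chrom &&
        out[[j]]$iFirst <= out[[i]]$iFirst &&
        out[[j]]$iLast >= out[[i]]$iLast &&
        all(out[[i]]$carriers %in% out[[j]]$carriers) &&
        !(out[[j]]$iFirst == out[[i]]$iFirst &&
          out[[j]]$iLast == out[[i]]$iLast &&
          length(out[[j]]$carriers) == length(out[[i]]$carriers)))
      keep[i] <- FALSE
  }
  out <- out[keep]
  iF <- vapply(out, `[[`, numeric(1), "iFirst")
  iL <- vapply(out, `[[`, numeric(1), "iLast")
  GenomicRanges::GRanges(
    seqnames = vapply(out, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(start = mk$pos[iF], end = mk$pos[iL]),
    carriers = IRanges::CharacterList(lapply(out, `[[`, "carriers")),
    N = vapply(out, function(o) length(o$carriers), integer(1)),
    iFirst = as.integer(iF), iLast = as.integer(iL),
    nSnps = as.integer(iL - iF + 1L))
}


#' Probability that N of T patients share a homozygous region by chance
#'
#' The multi-patient homozygosity-by-chance parameter: with each of T
#' patients independently carrying the region homozygous with
#' probability p (the per-individual \eqn{HBC_s = HF^2}), returns the
#' binomial upper tail \eqn{P(X \ge N)}, \eqn{X \sim Binomial(T, p)}.
#' Reduces to \eqn{HBC_s} at N = T = 1.
#'
#' @param p per-individual probability (representative HF^2), in (0, 1)
#' @param N number of patients sharing the region (0 returns 1)
#' @param T total number of patients considered
#' @return the probability \eqn{HBC_m}
#' @examples
#' hbcM(0.1, 2, 3)          # 0.028
#' hbcM(0.25, 1, 1)         # = HBC_s
#' @export
hbcM <- function(p, N, T) {
  n <- max(length(p), length(N), length(T))
  p <- rep_len(p, n); N <- rep_len(N, n); T <- rep_len(T, n)
  if (any(N > T)) stop("N must not exceed T")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  out <- stats::pbinom(N - 1, T, p, lower.tail = FALSE)
  out[N <= 0] <- 1
  out
}

#' Score shared regions with HBC_m
#'
#' Re-evaluates each carrier's haplotype frequency over the consensus
#' interval only (not the carrier's full run) and combines them into the
#' multi-patient statistic \eqn{HBC_m}. The representative
#' per-individual probability is the maximum carrier \eqn{HF^2} over
#' the interval (conservative) or their geometric mean.
#'
#' @param shared `GRanges` from [findSharedRegions()]
#' @param panel the [GenotypePanel] holding carriers
#' @param table [PairwiseHFTable] from controls
#' @param T total number of patients considered
#' @param pRule `"max"` (default, conservative) or `"geomean"`
#' @param capN when set, evaluate \eqn{HBC_m} using at most `capN`
#'   carriers (the ones with smallest \eqn{HF^2}); used by the
#'   multi-patient null, which records the best region shared by N or
#'   fewer controls
#' @return `shared` with metadata columns `pRep`, `hbcM`, `T` and
#'   `score` (\eqn{-\log_{10} HBC_m})
#' @export
scoreSharedRegions <- function(shared, panel, table, T,
                               pRule = c("max", "geomean"), capN = NULL) {
  pRule <- match.arg(pRule)
  mc <- S4Vectors::mcols(shared)
  n <- length(shared)
  pRep <- numeric(n); hm <- numeric(n); Neff <- integer(n)
  for (r in seq_len(n)) {
    carr <- mc$carriers[[r]]
    sub <- GenomicRanges::GRanges(
      seqnames = rep(as.character(GenomicRanges::seqnames(shared)[r]),
                     length(carr)),
      ranges = IRanges::IRanges(rep(GenomicRanges::start(shared)[r],
                                    length(carr)),
                                rep(GenomicRanges::end(shared)[r],
                                    length(carr))),
      individual = carr,
      iFirst = rep(mc$iFirst[r], length(carr)),
      iLast = rep(mc$iLast[r], length(carr)))
    sc <- scoreRegions(sub, panel, table)
    hf2 <- sort(S4Vectors::mcols(sc)$hbcS)
    Neff[r] <- if (is.null(capN)) length(carr) else min(capN, length(carr))
    hf2 <- hf2[seq_len(Neff[r])]
    pRep[r] <- if (pRule == "max") max(hf2) else exp(mean(log(hf2)))
    pRep[r] <- min(max(pRep[r], .Machine$double.xmin), 1 - 1e-12)
    hm[r] <- hbcM(pRep[r], Neff[r], T)
  }
  mc$pRep <- pRep
  mc$hbcM <- hm
  mc$T <- rep(as.integer(T), n)
  mc$Neff <- Neff
  mc$score <- -log10(hm)
  S4Vectors::mcols(shared) <- mc
  shared
}

#' Affected sib-pair adjustment
#'
#' For affected sib pairs, each family contributes the smaller
#' \eqn{HF^2} of its two siblings as the family statistic, and because a
#' sib pair shares both alleles identical by descent with probability
#' 1/4, the final P-value is multiplied by \eqn{(1/4)^N} where N is the
#' number of families sharing the founder homozygous allele.
#'
#' @param hf2Sib1,hf2Sib2 per-family \eqn{HF^2} of the two affected
#'   siblings (equal-length vectors, one entry per family)
#' @param N number of sharing families
#' @return list with `familyStat` (pmin of the two) and `ibdFactor`
#'   (\eqn{(1/4)^N})
#' @examples
#' sibpairAdjust(1e-6, 1e-4, N = 1)
#' @export
sibpairAdjust <- function(hf2Sib1, hf2Sib2, N) {
  if (length(hf2Sib1) != length(hf2Sib2))
    stop("each family needs exactly two affected siblings")
  list(familyStat = pmin(hf2Sib1, hf2Sib2), ibdFactor = 0.25^N)
}
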