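# Founder-allele inheritance: a mutation-carrying haplotype is assigned
# to an ancestor and transmitted through g generations of meioses, each
# meiosis drawing crossovers as a Poisson process on the genetic map
# (Haldane, no interference) and keeping the segment containing the
# focal locus (the transmission of the focal allele is conditioned on at
# every generation). An affected individual inherits two copies through
# independent paths; its homozygous tract is the intersection of the two
# surviving segments.

#' Sex-averaged autosomal genetic map lengths
#'
#' A bundled 22-row table of human autosome genetic lengths (cM),
#' sex-averaged, used by [cousinSharingProbability()] when no map is
#' supplied. Total ~35.5 Morgans.
#'
#' @return data.frame with columns `chrom`, `lengthCM`
#' @export
autosomeGeneticMap <- function() {
  data.frame(chrom = as.character(1:22),
             lengthCM = c(286.3, 268.6, 223.4, 214.6, 204.1, 192.0, 187.2,
                          168.0, 166.4, 181.0, 158.2, 174.7, 125.9, 120.8,
                          141.9, 134.0, 128.5, 117.5, 107.9, 108.2, 62.8,
                          74.1))
}

#' Transmit a founder segment through g meioses
#'
#' Starting from a whole founder chromosome, applies `g` independent
#' meioses; each draws crossovers as a Poisson process (rate 1 per
#' Morgan) along the chromosome and keeps the segment containing the
#' focal locus. Returns the surviving founder interval around the focal
#' locus, in cM. `g = 0` returns the full chromosome.
#'
#' @param g number of generations (meioses) of transmission
#' @param chromLengthCM genetic length of the chromosome, cM
#' @param focalCM position of the focal (mutation) locus, cM
#' @return numeric `c(start, end)` in cM
#' @examples
#' set.seed(1)
#' transmitFounderSegment(10, 150, 75)
#' @export
transmitFounderSegment <- function(g, chromLengthCM, focalCM) {
  if (focalCM < 0 || focalCM > chromLengthCM)
    stop("focal locus outside the chromosome")
  lo <- 0; hi <- chromLengthCM
  if (g == 0) return(c(lo, hi))
  for (i in seq_len(g)) {
    x <- crossoverPoints(chromLengthCM)
    lo <- max(lo, x[x < focalCM], -Inf)
    hi <- min(hi, x[x > focalCM], Inf)
    lo <- max(lo, 0); hi <- min(hi, chromLengthCM)
  }
  c(lo, hi)
}

crossoverPoints <- function(lengthCM) {
  n <- stats::rpois(1L, lengthCM / 100)
  if (n == 0L) numeric() else sort(stats::runif(n, 0, lengthCM))
}

# one more meiosis applied to an already-shortened interval
shortenSegment <- function(seg, chromLengthCM, focalCM) {
  x <- crossoverPoints(chromLengthCM)
  c(max(seg[1], x[x < focalCM], 0),
    min(seg[2], x[x > focalCM], chromLengthCM))
}

#' Simulate an affected individual carrying two founder copies
#'
#' Builds the genotypes of an "affected" individual that inherited two
#' copies of a founder haplotype through two independent g-generation
#' inheritance paths. The homozygous tract is the intersection of the
#' two surviving founder segments; background haplotypes are drawn from
#' the model's generating process. If the intersection covers fewer than
#' `minPlantedSnps` markers the transmission is redrawn (a message
#' records the resampling), mirroring the conditioning on an affected
#' who actually inherited a homozygous region.
#'
#' @param model a [populationModel()] (pool mode: the founder haplotype
#'   is a pool haplotype)
#' @param g generations of meioses per inheritance path
#' @param founderHap index of the founder haplotype in the pool
#'   (default: drawn by pool frequency)
#' @param focalMarker global index of the focal marker (default: drawn
#'   uniformly)
#' @param minPlantedSnps smallest acceptable homozygous tract, markers
#' @param maxResample cap on redraws before giving up
#' @return list with `genotype` (dosage vector), `haplotypes` (2 x
#'   markers), `iFirst`, `iLast` (planted tract, global marker
#'   indices), `focalMarker`, `founderHap`, `resamples`
#' @export
makeAffected <- function(model, g, founderHap = NULL, focalMarker = NULL,
                         minPlantedSnps = 25L, maxResample = 100L) {
  if (model$mode != "pool")
    stop("makeAffected needs a pool-mode model (founder haplotypes)")
  mk <- model$markers
  co <- chromOffsets(mk)
  if (is.null(founderHap))
    founderHap <- sample.int(nrow(model$pool), 1L, prob = model$poolW)
  if (is.null(focalMarker))
    focalMarker <- sample.int(nrow(mk), 1L)
  ci <- match(mk$chrom[focalMarker], co$chrom)
  idx <- co$from[ci]:co$to[ci]
  cm0 <- mk$cM[co$from[ci]]
  len <- mk$cM[co$to[ci]] - cm0
  focal <- mk$cM[focalMarker] - cm0
  resamples <- 0L
  repeat {
    s1 <- transmitFounderSegment(g, len, focal)
    s2 <- transmitFounderSegment(g, len, focal)
    seg <- c(max(s1[1], s2[1]), min(s1[2], s2[2]))
    inSeg <- idx[mk$cM[idx] - cm0 >= seg[1] & mk$cM[idx] - cm0 <= seg[2]]
    if (length(inSeg) >= minPlantedSnps) break
    resamples <- resamples + 1L
    if (resamples > maxResample)
      stop("planted tract below ", minPlantedSnps,
           " markers after ", maxResample, " redraws; lower g or minPlantedSnps")
  }
  if (resamples > 0)
    message("makeAffected: ", resamples, " transmission redraw(s)")
  h1 <- drawMosaicHaplotype(model)$hap
  h2 <- drawMosaicHaplotype(model)$hap
  h1[inSeg] <- model$pool[founderHap, inSeg]
  h2[inSeg] <- model$pool[founderHap, inSeg]
  list(genotype = h1 + h2, haplotypes = rbind(h1, h2),
       iFirst = inSeg[1], iLast = inSeg[length(inSeg)],
       focalMarker = focalMarker, founderHap = founderHap,
       resamples = resamples)
}

#' Simulate a case/control study with planted founder tracts
#'
#' Generates a control panel and a case panel in which `nCarriers` of
#' the `nCases` cases are affected individuals carrying two copies of
#' the same founder haplotype (independent inheritance paths from one
#' ancestor), while the remaining cases are plain draws from the
#' population.
#'
#' @param model a pool-mode [populationModel()]
#' @param nControls,nCases panel sizes
#' @param nCarriers number of cases sharing the planted founder tract
#' @param g generations of meioses per path
#' @param seed seed for the whole study draw
#' @param minPlantedSnps passed to [makeAffected()]
#' @return list with `controls`, `cases` (both [GenotypePanel]),
#'   `carrierIds`, `planted` (data.frame of per-carrier iFirst/iLast),
#'   `founderHap`, `focalMarker`
#' @export
simulateStudy <- function(model, nControls, nCases, nCarriers, g,
                          seed = 1L, minPlantedSnps = 25L) {
  set.seed(seed)
  controls <- generatePanel(model, nControls, role = "control",
                            idPrefix = "ctrl")$panel
  founderHap <- sample.int(nrow(model$pool), 1L, prob = model$poolW)
  focalMarker <- sample.int(nrow(model$markers), 1L)
  gcases <- matrix(0L, nCases, nrow(model$markers))
  planted <- data.frame(iFirst = integer(nCarriers), iLast = integer(nCarriers))
  for (k in seq_len(nCarriers)) {
    aff <- makeAffected(model, g, founderHap = founderHap,
                        focalMarker = focalMarker,
                        minPlantedSnps = minPlantedSnps)
    gcases[k, ] <- aff$genotype
    planted$iFirst[k] <- aff$iFirst
    planted$iLast[k] <- aff$iLast
  }
  if (nCases > nCarriers) {
    bg <- generatePanel(model, nCases - nCarriers)$panel
    gcases[(nCarriers + 1):nCases, ] <- genotypes(bg)
  }
  ind <- data.frame(id = sprintf("case%04d", seq_len(nCases)),
                    role = "case", family = NA_character_)
  list(controls = controls,
       cases = GenotypePanel(gcases, model$markers, ind),
       carrierIds = ind$id[seq_len(nCarriers)], planted = planted,
       founderHap = founderHap, focalMarker = focalMarker)
}

#' Simulate affected sib-pair families
#'
#' Carrier families descend from the founder through both parents: each
#' parent's founder segment is transmitted over g-1 generations, and one
#' further (conditioned) meiosis per parent produces each sibling's
#' inherited copy, so the two siblings carry overlapping but distinct
#' homozygous tracts. Siblings of non-carrier families are proper sibs:
#' both are meiotic products of the same two simulated parents.
#'
#' @param model a pool-mode [populationModel()]
#' @param nFamilies total number of affected sib-pair families
#' @param nCarrierFamilies number of families segregating the founder
#'   haplotype
#' @param g generations from the founder to each parent (+1 meiosis to
#'   the sibs)
#' @param seed seed
#' @param minPlantedSnps smallest acceptable per-sib homozygous tract
#' @return list with `cases` (a [GenotypePanel] of 2*nFamilies sibs,
#'   family column set), `carrierFamilies`, `planted` (per carrier sib)
#' @export
simulateSibPairs <- function(model, nFamilies, nCarrierFamilies, g,
                             seed = 1L, minPlantedSnps = 25L) {
  set.seed(seed)
  mk <- model$markers
  m <- nrow(mk)
  co <- chromOffsets(mk)
  founderHap <- sample.int(nrow(model$pool), 1L, prob = model$poolW)
  focalMarker <- sample.int(m, 1L)
  ci <- match(mk$chrom[focalMarker], co$chrom)
  idx <- co$from[ci]:co$to[ci]
  cm0 <- mk$cM[co$from[ci]]
  len <- mk$cM[co$to[ci]] - cm0
  focal <- mk$cM[focalMarker] - cm0

  geno <- matrix(0L, 2L * nFamilies, m)
  fam <- rep(sprintf("fam%03d", seq_len(nFamilies)), each = 2L)
  ids <- sprintf("%s_s%d", fam, rep(1:2, nFamilies))
  planted <- data.frame(id = character(), iFirst = integer(),
                        iLast = integer())
  for (f in seq_len(nFamilies)) {
    rows <- c(2L * f - 1L, 2L * f)
    if (f <= nCarrierFamilies) {
      repeat {
        segF <- transmitFounderSegment(g - 1L, len, focal)
        segM <- transmitFounderSegment(g - 1L, len, focal)
        sibSegs <- lapply(1:2, function(s) {
          a <- shortenSegment(segF, len, focal)
          b <- shortenSegment(segM, len, focal)
          c(max(a[1], b[1]), min(a[2], b[2]))
        })
        nIn <- vapply(sibSegs, function(sg)
          sum(mk$cM[idx] - cm0 >= sg[1] & mk$cM[idx] - cm0 <= sg[2]),
          numeric(1))
        if (all(nIn >= minPlantedSnps)) break
      }
      for (s in 1:2) {
        h1 <- drawMosaicHaplotype(model)$hap
        h2 <- drawMosaicHaplotype(model)$hap
        sg <- sibSegs[[s]]
        inSeg <- idx[mk$cM[idx] - cm0 >= sg[1] & mk$cM[idx] - cm0 <= sg[2]]
        h1[inSeg] <- model$pool[founderHap, inSeg]
        h2[inSeg] <- model$pool[founderHap, inSeg]
        geno[rows[s], ] <- h1 + h2
        planted <- rbind(planted,
                         data.frame(id = ids[rows[s]], iFirst = inSeg[1],
                                    iLast = inSeg[length(inSeg)]))
      }
    } else {
      pat <- rbind(drawMosaicHaplotype(model)$hap, drawMosaicHaplotype(model)$hap)
      mat <- rbind(drawMosaicHaplotype(model)$hap, drawMosaicHaplotype(model)$hap)
      for (s in 1:2)
        geno[rows[s], ] <- meioseHaplotypes(pat, mk) + meioseHaplotypes(mat, mk)
    }
  }
  ind <- data.frame(id = ids, role = "case", family = fam)
  list(cases = GenotypePanel(geno, mk, ind),
       carrierFamilies = unique(fam)[seq_len(nCarrierFamilies)],
       planted = planted, founderHap = founderHap,
       focalMarker = focalMarker)
}

# recombine a parent's two haplotypes into one gamete on the marker grid
meioseHaplotypes <- function(haps, mk) {
  out <- integer(ncol(haps))
  co <- chromOffsets(mk)
  for (ci in seq_along(co$chrom)) {
    idx <- co$from[ci]:co$to[ci]
    cm <- mk$cM[idx]
    x <- crossoverPoints(cm[length(cm)] - cm[1]) + cm[1]
    phase <- (sample(0:1, 1L) + findInterval(cm, x)) %% 2L
    out[idx] <- ifelse(phase == 0L, haps[1L, idx], haps[2L, idx])
  }
  out
}

# ---- cousin IBD sharing ---------------------------------------------------

#' Probability that k-th cousins share an autosomal IBD segment
#'
#' Monte-Carlo estimate of the probability that `nRelatives` k-th
#' cousins, descending from one common ancestral couple through
#' distinct children, all carry an overlapping chromosomal segment
#' inherited from the same ancestral haplotype. Crossovers are a
#' Poisson process on genetic distance (no interference) over the 22
#' autosomes; each relative's lineage haplotype is tracked as a mosaic
#' labelled by its founder-haplotype origin (or none).
#'
#' @param degree cousin degree k (1 = first cousins; 0 = siblings,
#'   whose sharing probability is 1 for practical purposes)
#' @param nRelatives number of relatives that must all share (2 or 3)
#' @param replicates Monte-Carlo replicates
#' @param map genetic map, data.frame(chrom, lengthCM); default
#'   [autosomeGeneticMap()]
#' @param seed integer seed
#' @return list with `probability`, `se` (binomial standard error),
#'   `hits`, `replicates`
#' @examples
#' cousinSharingProbability(1, 2, replicates = 500, seed = 1)
#' @export
cousinSharingProbability <- function(degree, nRelatives = 2L,
                                     replicates = 20000L,
                                     map = autosomeGeneticMap(),
                                     seed = 1L) {
  stopifnot(degree >= 0, nRelatives >= 2)
  set.seed(seed)
  lens <- map$lengthCM
  hits <- 0L
  for (rep in seq_len(replicates)) {
    found <- FALSE
    for (L in lens) {
      tracks <- vector("list", nRelatives)
      ok <- TRUE
      for (cc in seq_len(nRelatives)) {
        t <- cousinLabelTrack(L, degree)
        if (is.null(t)) { ok <- FALSE; break }
        tracks[[cc]] <- t
      }
      if (!ok) next
      if (labelledOverlap(tracks)) { found <- TRUE; break }
    }
    if (found) hits <- hits + 1L
  }
  p <- hits / replicates
  list(probability = p, se = sqrt(p * (1 - p) / replicates),
       hits = hits, replicates = replicates)
}

# Labelled founder-origin segments of one k-th cousin's lineage
# haplotype on a chromosome of length L. The descent chain below the
# ancestral couple comprises: the couple->child meioses (phase
# telegraphs bF over founder haplotypes 1/2 and bM over 3/4), the
# child->grandchild meiosis mixing the child's two haplotypes (bPM),
# and k-1 further meioses that mix with non-founder DNA (the segment is
# founder-origin only where all of these are in the lineage state).
# Siblings (k = 0) carry both child haplotypes; handled by the caller
# via two tracks. Returns matrix (start, end, label) or NULL.
cousinLabelTrack <- function(L, k) {
  if (k == 0L) {                      # a child of the couple: two haps
    tF <- phaseTelegraph(L)
    tM <- phaseTelegraph(L)
    segs <- rbind(labelSegments(L, tF, offset = 0L),
                  labelSegments(L, tM, offset = 2L))
    return(segs)
  }
  nOut <- k - 1L
  pts <- vector("list", nOut)
  init <- integer(nOut)
  for (i in seq_len(nOut)) {
    n <- stats::rpois(1L, L / 100)
    s <- sample.int(2L, 1L) - 1L      # 1 = outside lineage
    if (n == 0L && s == 1L) return(NULL)
    pts[[i]] <- if (n > 0L) sort(stats::runif(n, 0, L)) else numeric()
    init[i] <- s
  }
  # sweep: intervals where every outside-telegraph is in lineage state
  allp <- unlist(pts)
  ids <- rep.int(seq_len(nOut), vapply(pts, length, integer(1)))
  if (length(allp)) {
    o <- order(allp)
    allp <- allp[o]; ids <- ids[o]
  }
  state <- init
  wrong <- sum(state)
  bnd <- c(0, allp, L)
  nseg <- length(allp) + 1L
  segA <- numeric(0); segB <- numeric(0)
  for (j in seq_len(nseg)) {
    if (wrong == 0L) { segA <- c(segA, bnd[j]); segB <- c(segB, bnd[j + 1L]) }
    if (j <= length(allp)) {
      i <- ids[j]
      state[i] <- 1L - state[i]
      wrong <- wrong + if (state[i] == 1L) 1L else -1L
    }
  }
  if (!length(segA)) return(NULL)
  # merge adjacent lineage intervals
  keep <- c(TRUE, segA[-1] > segB[-length(segB)])
  grp <- cumsum(keep)
  segA <- tapply(segA, grp, min)
  segB <- tapply(segB, grp, max)
  # label: bPM chooses the child's paternal/maternal haplotype; bF/bM
  # choose the founder haplotype within it
  tPM <- phaseTelegraph(L)
  tF <- phaseTelegraph(L)
  tM <- phaseTelegraph(L)
  out <- NULL
  for (r in seq_along(segA)) {
    cuts <- c(tPM$pts, tF$pts, tM$pts)
    cuts <- sort(cuts[cuts > segA[r] & cuts < segB[r]])
    b <- c(segA[r], cuts, segB[r])
    mid <- (b[-length(b)] + b[-1]) / 2
    side <- telegraphState(tPM, mid)
    lab <- ifelse(side == 0L,
                  1L + telegraphState(tF, mid),
                  3L + telegraphState(tM, mid))
    out <- rbind(out, cbind(b[-length(b)], b[-1], lab))
  }
  out
}

phaseTelegraph <- function(L) {
  n <- stats::rpois(1L, L / 100)
  list(pts = if (n > 0L) sort(stats::runif(n, 0, L)) else numeric(),
       init = sample.int(2L, 1L) - 1L)
}

telegraphState <- function(t, x) {
  (t$init + findInterval(x, t$pts)) %% 2L
}

# whole-chromosome labelled segments of one child haplotype (k = 0)
labelSegments <- function(L, t, offset) {
  b <- c(0, t$pts, L)
  mid <- (b[-length(b)] + b[-1]) / 2
  cbind(b[-length(b)], b[-1], offset + 1L + telegraphState(t, mid))
}

# do all tracks share a common position with a common label? exact
# interval intersection, label by label
labelledOverlap <- function(tracks) {
  cand <- tracks[[1]]
  for (t in tracks[-1]) {
    nxt <- NULL
    for (i in seq_len(nrow(cand))) {
      hit <- which(t[, 3] == cand[i, 3] &
                   t[, 1] < cand[i, 2] & t[, 2] > cand[i, 1])
      for (h in hit)
        nxt <- rbind(nxt, c(max(cand[i, 1], t[h, 1]),
                            min(cand[i, 2], t[h, 2]), cand[i, 3]))
    }
    if (is.null(nxt)) return(FALSE)
    cand <- nxt
  }
  TRUE
}
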