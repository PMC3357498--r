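# The four analysis modes (single patient, multi-patient sharing,
# case-control, affected sib pairs) plus study simulation, bound into a
# single configurable entry point used by the command-line script.

#' Run a homozygosity-mapping analysis
#'
#' Drives the full pipeline for one of five modes:
#' \describe{
#'   \item{single}{each case is analysed alone: its runs of
#'     homozygosity are scored by [scoreRegions()] and measured against
#'     the best regions of the controls ([singlePatientNull()]).}
#'   \item{multi, casecontrol}{regions of shared homozygosity across
#'     the cases are scored with \eqn{HBC_m} and measured against
#'     [multiPatientNull()]. The two modes differ only in intent (a few
#'     Mendelian patients vs. a large case-control panel).}
#'   \item{sibpair}{cases are affected sib pairs (family column);
#'     within-family shared homozygosity is collapsed to one region set
#'     per family, cross-family sharing is scored with the smaller
#'     sibling \eqn{HF^2} per family, and the final P-value carries the
#'     \eqn{(1/4)^N} sib-pair IBD factor.}
#'   \item{simulate}{writes a synthetic study (controls + planted
#'     cases) in PLINK text format with a truth sidecar.}
#' }
#'
#' @param config a list (see [defaultConfig()]) with elements `mode`,
#'   `cases`, `controls` ([GenotypePanel] objects or file paths),
#'   run-calling thresholds `minSnps`, `maxHet`, `maxMissing`,
#'   `minCarriers`, `N`, `rounds`, `seed`, `exclusion`, `leaveOneOut`,
#'   `nullCache`, `out` (output prefix or NULL), and for
#'   mode = "simulate": `model`, `nControls`, `nCases`, `nCarriers`,
#'   `g`.
#' @return a list with mode-dependent elements: scored `regions`
#'   (`GRanges` with `empiricalP`), the `null` distribution used, and
#'   the paths written (when `out` is set). Every run is reproducible
#'   from its config and seed; the config is echoed to `<out>.log`.
#' @export
runAnalysis <- function(config) {
  config <- utils::modifyList(defaultConfig(), config)
  mode <- match.arg(config$mode,
                    c("single", "multi", "casecontrol", "sibpair", "simulate"))
  if (mode == "simulate") return(runSimulate(config))
  cases <- loadPanel(config$cases)
  controls <- loadPanel(config$controls)
  hp <- harmonize(cases, controls)
  cases <- hp$cases; controls <- hp$controls
  res <- switch(mode,
    single = runSingle(cases, controls, config),
    multi = ,
    casecontrol = runMulti(cases, controls, config),
    sibpair = runSibpair(cases, controls, config))
  if (!is.null(config$out)) {
    writeRegionTable(res$regions, paste0(config$out, ".regions.tsv"))
    if (!is.null(res$null))
      writeNullDistribution(res$null, paste0(config$out, ".null.tsv"))
    logCfg <- config[!vapply(config, is.object, logical(1))]
    logCfg <- logCfg[!names(logCfg) %in% c("cases", "controls", "model")]
    writeLines(c(paste0("# ", format(Sys.time())),
                 paste(names(logCfg), vapply(logCfg, function(x)
                   paste(format(x), collapse = ","), character(1)),
                   sep = " = ")),
               paste0(config$out, ".log"))
    res$files <- paste0(config$out, c(".regions.tsv", ".null.tsv", ".log"))
  }
  res
}

#' Default run configuration
#'
#' All thresholds of [runAnalysis()] with their defaults, so published
#' runs are self-describing.
#' @return named list
#' @export
defaultConfig <- function() {
  list(mode = "single", cases = NULL, controls = NULL,
       minSnps = 25L, maxHet = 0L, maxMissing = 2L,
       minCarriers = 2L, N = NULL, T = NULL,
       rounds = 200L, seed = 1L, exclusion = TRUE, leaveOneOut = TRUE,
       nullCache = NULL, out = NULL,
       model = NULL, nControls = 100L, nCases = 1L, nCarriers = 1L, g = 10L)
}

loadPanel <- function(x) {
  if (is.character(x)) readPanel(x) else x
}

# put cases and controls on one harmonized marker map
harmonize <- function(cases, controls) {
  if (identical(markers(cases)$id, markers(controls)$id))
    return(list(cases = cases, controls = controls))
  ind <- individuals(cases)
  merged <- mergePanels(cases, controls)
  isCase <- individuals(merged)$id %in% ind$id
  list(cases = merged[which(isCase)], controls = merged[which(!isCase)])
}

runSingle <- function(cases, controls, cfg) {
  ctrlIds <- individuals(controls)$id
  fullTable <- pairwiseHFTable(controls)
  out <- list()
  nullUsed <- NULL
  for (id in individuals(cases)$id) {
    inCtrl <- id %in% ctrlIds
    ctrl <- if (inCtrl) controls[setdiff(ctrlIds, id)] else controls
    tab <- if (inCtrl) pairwiseHFTable(ctrl) else fullTable
    null <- if (!is.null(cfg$nullCache) && file.exists(cfg$nullCache) &&
                !inCtrl) {
      readNullDistribution(cfg$nullCache)
    } else {
      singlePatientNull(ctrl, table = tab, minSnps = cfg$minSnps,
                        maxHet = cfg$maxHet, maxMissing = cfg$maxMissing,
                        leaveOneOut = cfg$leaveOneOut)
    }
    nullUsed <- null
    regions <- callROH(cases, id, minSnps = cfg$minSnps,
                       maxHet = cfg$maxHet, maxMissing = cfg$maxMissing)
    if (length(regions)) {
      regions <- scoreRegions(regions, cases, tab)
      S4Vectors::mcols(regions)$empiricalP <-
        empiricalP(S4Vectors::mcols(regions)$score, null)
    }
    out[[id]] <- regions
  }
  regions <- do.call(c, unname(out))
  regions <- regions[order(S4Vectors::mcols(regions)$empiricalP,
                           -S4Vectors::mcols(regions)$score)]
  if (!is.null(cfg$nullCache) && !file.exists(cfg$nullCache) &&
      !is.null(nullUsed))
    writeNullDistribution(nullUsed, cfg$nullCache)
  list(regions = regions, null = nullUsed)
}

runMulti <- function(cases, controls, cfg) {
  T <- if (is.null(cfg$T)) nIndividuals(cases) else cfg$T
  table <- pairwiseHFTable(controls)
  roh <- callROH(cases, minSnps = cfg$minSnps, maxHet = cfg$maxHet,
                 maxMissing = cfg$maxMissing)
  shared <- findSharedRegions(roh, cases, minCarriers = cfg$minCarriers,
                              minSnps = cfg$minSnps)
  if (!length(shared))
    return(list(regions = shared, null = NULL))
  N <- if (is.null(cfg$N)) max(S4Vectors::mcols(shared)$N) else cfg$N
  shared <- scoreSharedRegions(shared, cases, table, T = T, capN = N)
  null <- if (!is.null(cfg$nullCache) && file.exists(cfg$nullCache)) {
    readNullDistribution(cfg$nullCache)
  } else {
    multiPatientNull(controls, N = N, T = T, rounds = cfg$rounds,
                     seed = cfg$seed, table = table,
                     exclusion = cfg$exclusion, minSnps = cfg$minSnps,
                     maxHet = cfg$maxHet, maxMissing = cfg$maxMissing)
  }
  if (!is.null(cfg$nullCache) && !file.exists(cfg$nullCache))
    writeNullDistribution(null, cfg$nullCache)
  S4Vectors::mcols(shared)$empiricalP <-
    empiricalP(S4Vectors::mcols(shared)$score, null)
  o <- order(S4Vectors::mcols(shared)$empiricalP,
             -S4Vectors::mcols(shared)$score)
  list(regions = shared[o], null = null)
}

# ---- sib pairs ------------------------------------------------------------

# regions where both siblings of each family are homozygous for the
# same allele; returns per-family GRanges plus the family pseudo-panel
familyConsensus <- function(panel, cfg) {
  ind <- individuals(panel)
  if (any(is.na(ind$family)))
    stop("sib-pair mode needs a family id for every case individual")
  fams <- split(ind$id, ind$family)
  bad <- names(fams)[lengths(fams) != 2]
  if (length(bad))
    stop("sib-pair mode needs exactly 2 genotyped affected sibs per family; ",
         "offending families: ", paste(bad, collapse = ", "))
  g <- genotypes(panel)
  mk <- markers(panel)
  pseudo <- matrix(NA_integer_, length(fams), nrow(mk))
  regs <- list()
  for (f in seq_along(fams)) {
    sibs <- fams[[f]]
    roh <- callROH(panel, sibs, minSnps = cfg$minSnps, maxHet = cfg$maxHet,
                   maxMissing = cfg$maxMissing)
    shr <- findSharedRegions(roh, panel, minCarriers = 2L,
                             minSnps = cfg$minSnps)
    if (!length(shr)) next
    mc <- S4Vectors::mcols(shr)
    rows <- match(sibs, ind$id)
    for (r in seq_along(shr)) {
      span <- mc$iFirst[r]:mc$iLast[r]
      cons <- g[rows[1], span]
      nas <- is.na(cons) | cons == 1L
      cons[nas] <- g[rows[2], span][nas]
      cons[!is.na(cons) & cons == 1L] <- NA_integer_
      pseudo[f, span] <- cons
      regs[[length(regs) + 1L]] <-
        data.frame(family = names(fams)[f], chrom = mc$iFirst[r],
                   iFirst = mc$iFirst[r], iLast = mc$iLast[r])
    }
  }
  regDf <- if (length(regs)) do.call(rbind, regs) else NULL
  pp <- GenotypePanel(pseudo, mk, data.frame(id = names(fams),
                                             role = "case",
                                             family = names(fams)))
  list(pseudo = pp, regions = regDf, families = names(fams), famMembers = fams)
}

# cross-family sharing of within-family homozygous regions, scored with
# the smaller sibling HF^2 per family
sibpairSharedScores <- function(panel, cfg, table, minCarriers = 1L) {
  fc <- familyConsensus(panel, cfg)
  if (is.null(fc$regions)) return(NULL)
  mk <- markers(panel)
  fr <- GenomicRanges::GRanges(
    seqnames = mk$chrom[fc$regions$iFirst],
    ranges = IRanges::IRanges(mk$pos[fc$regions$iFirst],
                              mk$pos[fc$regions$iLast]),
    individual = fc$regions$family,
    iFirst = fc$regions$iFirst, iLast = fc$regions$iLast,
    nSnps = fc$regions$iLast - fc$regions$iFirst + 1L,
    nHet = 0L, nMissing = 0L)
  cross <- findSharedRegions(fr, fc$pseudo, minCarriers = minCarriers,
                             minSnps = cfg$minSnps)
  if (!length(cross)) return(NULL)
  mc <- S4Vectors::mcols(cross)
  Tfam <- length(fc$families)
  n <- length(cross)
  pRep <- numeric(n); hm <- numeric(n)
  for (r in seq_len(n)) {
    famStat <- vapply(mc$carriers[[r]], function(fid) {
      sibs <- fc$famMembers[[fid]]
      sub <- GenomicRanges::GRanges(
        seqnames = rep(as.character(GenomicRanges::seqnames(cross)[r]), 2),
        ranges = IRanges::IRanges(rep(GenomicRanges::start(cross)[r], 2),
                                  rep(GenomicRanges::end(cross)[r], 2)),
        individual = sibs, iFirst = rep(mc$iFirst[r], 2),
        iLast = rep(mc$iLast[r], 2))
      sc <- scoreRegions(sub, panel, table)
      min(S4Vectors::mcols(sc)$hbcS)     # smaller sibling HF^2
    }, numeric(1))
    pRep[r] <- min(max(max(famStat), .Machine$double.xmin), 1 - 1e-12)
    hm[r] <- hbcM(pRep[r], length(famStat), Tfam)
  }
  mc$pRep <- pRep
  mc$hbcM <- hm
  mc$T <- Tfam
  mc$score <- -log10(hm)
  S4Vectors::mcols(cross) <- mc
  cross
}

runSibpair <- function(cases, controls, cfg) {
  table <- pairwiseHFTable(controls)
  scored <- sibpairSharedScores(cases, cfg, table, minCarriers = 1L)
  if (is.null(scored))
    return(list(regions = emptyRegionGRanges(), null = NULL))
  # null: random control pairs stand in for unrelated "sib" pairs
  Tfam <- length(unique(individuals(cases)$family))
  null <- sibpairNull(controls, Tfam, rounds = cfg$rounds, seed = cfg$seed,
                      table = table, cfg = cfg)
  mc <- S4Vectors::mcols(scored)
  p <- empiricalP(mc$score, null) * 0.25^mc$N
  mc$empiricalP <- pmin(p, 1)
  S4Vectors::mcols(scored) <- mc
  o <- order(mc$empiricalP, -mc$score)
  list(regions = scored[o], null = null)
}

#' Sib-pair null distribution
#'
#' Monte-Carlo null for the sib-pair mode: in each round 2T controls
#' are drawn and paired into T pseudo-families, the cross-family
#' statistic is computed exactly as for real sib pairs, and the best
#' \eqn{-\log_{10} HBC_m} is recorded. The \eqn{(1/4)^N} IBD factor is
#' not part of the null (the pseudo-pairs are unrelated); it multiplies
#' the case P-value afterwards.
#'
#' @param controls control [GenotypePanel]
#' @param T number of families in the case analysis
#' @param rounds Monte-Carlo rounds
#' @param seed integer seed
#' @param table precomputed [PairwiseHFTable]
#' @param cfg run configuration (ROH thresholds)
#' @return a [NullDistribution] with mode `"sibpair"`
#' @export
sibpairNull <- function(controls, T, rounds = 200L, seed = 1L,
                        table = NULL, cfg = defaultConfig()) {
  ind <- individuals(controls)
  if (2 * T > nrow(ind))
    stop("need at least 2*T controls for the sib-pair null")
  if (is.null(table)) table <- pairwiseHFTable(controls)
  set.seed(seed)
  stats <- numeric(rounds)
  for (r in seq_len(rounds)) {
    draw <- sample(ind$id, 2 * T)
    sub <- controls[draw]
    indSub <- individuals(sub)
    indSub$family <- rep(sprintf("null%03d", seq_len(T)), each = 2)
    pseudo <- newGenotypePanel(genotypes(sub), markers(sub), indSub)
    sc <- sibpairSharedScores(pseudo, cfg, table, minCarriers = 1L)
    stats[r] <- if (is.null(sc)) 0 else max(S4Vectors::mcols(sc)$score)
  }
  new("NullDistribution", mode = "sibpair", stats = sort(stats),
      seed = as.integer(seed),
      params = list(T = T, M = rounds, minSnps = cfg$minSnps,
                    maxHet = cfg$maxHet, maxMissing = cfg$maxMissing))
}

runSimulate <- function(cfg) {
  model <- if (is.null(cfg$model)) populationModel(seed = cfg$seed) else cfg$model
  st <- simulateStudy(model, nControls = cfg$nControls, nCases = cfg$nCases,
                      nCarriers = cfg$nCarriers, g = cfg$g, seed = cfg$seed,
                      minPlantedSnps = cfg$minSnps)
  out <- if (is.null(cfg$out)) tempfile("simstudy") else cfg$out
  writePanel(st$controls, paste0(out, ".controls"), format = "plink")
  writePanel(st$cases, paste0(out, ".cases"), format = "plink")
  mk <- markers(st$cases)
  truth <- data.frame(individual = st$carrierIds,
                      chrom = mk$chrom[st$planted$iFirst],
                      start_bp = mk$pos[st$planted$iFirst],
                      end_bp = mk$pos[st$planted$iLast],
                      founderHap = st$founderHap, g = cfg$g,
                      seed = cfg$seed)
  utils::write.table(truth, paste0(out, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(study = st,
       files = paste0(out, c(".controls.ped", ".controls.map",
                             ".cases.ped", ".cases.map", ".truth.tsv")))
}
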