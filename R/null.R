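# Monte-Carlo null distributions built from control genomes, and the
# conversion of region statistics into genome-wide empirical P-values.
# All statistics are compared on the -log10(HBC) scale (larger = more
# extreme) so that linear-scale underflow cannot create ties at zero.

#' Single-patient null distribution
#'
#' Records, for every control individual, the homozygous region with the
#' smallest \eqn{HF^2} anywhere in that control's genome (as
#' \eqn{-\log_{10} HBC_s}); these best-region statistics form the null
#' against which a patient's regions are measured. A control without any
#' qualifying run contributes the sentinel statistic \eqn{HBC_s = 1}
#' (score 0). By default each control is scored against a leave-one-out
#' frequency table (its own genotypes removed from the EM), so that
#' control statistics are out-of-sample in the same way a patient's are;
#' set `leaveOneOut = FALSE` to score in-sample.
#'
#' @param controls a [GenotypePanel] of controls
#' @param table optional precomputed [PairwiseHFTable] for the full
#'   panel (recomputed if missing); leave-one-out refits are warm-started
#'   from it
#' @param minSnps,maxHet,maxMissing run-calling thresholds, see
#'   [callROH()]
#' @param leaveOneOut drop each control from the EM when scoring its own
#'   genome
#' @return a [NullDistribution] with mode `"single"`, one statistic per
#'   control
#' @export
singlePatientNull <- function(controls, table = NULL, minSnps = 25L,
                              maxHet = 0L, maxMissing = 2L,
                              leaveOneOut = TRUE) {
  ind <- individuals(controls)
  if (nrow(ind) == 0) stop("empty control panel")
  if (nrow(ind) < 20)
    warning("fewer than 20 controls; the empirical null will be coarse")
  if (is.null(table)) table <- pairwiseHFTable(controls)
  regions <- callROH(controls, minSnps = minSnps, maxHet = maxHet,
                     maxMissing = maxMissing)
  mc <- S4Vectors::mcols(regions)
  stats <- numeric(nrow(ind))
  for (k in seq_len(nrow(ind))) {
    id <- ind$id[k]
    mine <- regions[mc$individual == id]
    if (length(mine) == 0) { stats[k] <- 0; next }
    tab <- if (leaveOneOut) {
      pairwiseHFTable(controls, exclude = id, warmStart = table)
    } else table
    sc <- scoreRegions(mine, controls, tab)
    stats[k] <- max(S4Vectors::mcols(sc)$score)
  }
  new("NullDistribution", mode = "single", stats = sort(stats),
      seed = NA_integer_,
      params = list(minSnps = minSnps, maxHet = maxHet,
                    maxMissing = maxMissing, leaveOneOut = leaveOneOut,
                    M = nrow(ind)))
}

#' Multi-patient null distribution
#'
#' Simulates the null of the multi-patient statistic: in each round, T
#' individuals are drawn without replacement from the controls, all
#' regions shared by N or fewer of them are evaluated with
#' [scoreSharedRegions()] (a region shared by more than N contributes
#' its N most extreme carriers), and the best \eqn{-\log_{10} HBC_m} of
#' the round is recorded. By default the recorded interval is then
#' masked (excluded from consideration) in subsequent rounds; disable
#' with `exclusion = FALSE`. Rounds with no qualifying region contribute
#' the sentinel statistic \eqn{HBC_m = 1}.
#'
#' @param controls a [GenotypePanel] of controls
#' @param N number of sharing patients in the case analysis
#' @param T number of patients considered (must not exceed the number of
#'   controls)
#' @param rounds number of Monte-Carlo rounds M
#' @param seed integer seed; the whole vector is reproducible
#'   bit-for-bit given the seed
#' @param table optional precomputed [PairwiseHFTable]
#' @param exclusion mask each round's recorded interval in later rounds
#' @param minSnps,maxHet,maxMissing run-calling thresholds
#' @return a [NullDistribution] with mode `"multi"` and M statistics
#' @export
multiPatientNull <- function(controls, N, T, rounds = 1000L, seed = 1L,
                             table = NULL, exclusion = TRUE,
                             minSnps = 25L, maxHet = 0L, maxMissing = 2L) {
  ind <- individuals(controls)
  if (T > nrow(ind)) stop("T exceeds the number of available controls")
  if (is.null(table)) table <- pairwiseHFTable(controls)
  regions <- callROH(controls, minSnps = minSnps, maxHet = maxHet,
                     maxMissing = maxMissing)
  mc <- S4Vectors::mcols(regions)
  set.seed(seed)
  stats <- numeric(rounds)
  masks <- GenomicRanges::GRanges()
  for (r in seq_len(rounds)) {
    draw <- sample(ind$id, T)
    sub <- regions[mc$individual %in% draw]
    if (length(masks) && length(sub))
      sub <- sub[!IRanges::overlapsAny(sub, masks)]
    if (length(sub) == 0) { stats[r] <- 0; next }
    shared <- findSharedRegions(sub, controls, minCarriers = 1L,
                                minSnps = minSnps)
    shared <- scoreSharedRegions(shared, controls, table, T = T, capN = N)
    best <- which.max(S4Vectors::mcols(shared)$score)
    stats[r] <- S4Vectors::mcols(shared)$score[best]
    if (exclusion)
      masks <- c(masks, GenomicRanges::granges(shared[best]))
  }
  new("NullDistribution", mode = "multi", stats = sort(stats),
      seed = as.integer(seed),
      params = list(N = N, T = T, M = rounds, exclusion = exclusion,
                    minSnps = minSnps, maxHet = maxHet,
                    maxMissing = maxMissing))
}

#' Genome-wide empirical P-value
#'
#' Converts a region statistic into an empirical P-value against a
#' Monte-Carlo null: the fraction of null statistics at least as extreme,
#' with an add-one pseudocount so a finite null can never give P = 0:
#' \deqn{P = (1 + \#\{null \ge stat\}) / (M + 1).}
#' Statistics are on the \eqn{-\log_{10} HBC} scale. For sib-pair
#' analyses the result is subsequently multiplied by \eqn{(1/4)^N}
#' (see [sibpairAdjust()]).
#'
#' @param stat statistic(s) of the region(s) being tested,
#'   \eqn{-\log_{10} HBC}
#' @param null a [NullDistribution]
#' @return empirical P-value(s) in (0, 1]
#' @examples
#' null <- new("NullDistribution", mode = "single",
#'             stats = sort(runif(999, 0, 10)), seed = 1L, params = list())
#' empiricalP(11, null)   # more extreme than every null entry -> 1/1000
#' @export
empiricalP <- function(stat, null) {
  M <- length(null@stats)
  vapply(stat, function(s) (1 + sum(null@stats >= s)) / (M + 1), numeric(1))
}

#' Null-distribution cache
#'
#' Writes/restores a [NullDistribution] as TSV with a header line
#' recording mode, round count, seed and run parameters.
#'
#' @param null a [NullDistribution]
#' @param file path
#' @export
writeNullDistribution <- function(null, file) {
  hdr <- sprintf("# mode=%s M=%d seed=%s %s", null@mode, length(null@stats),
                 null@seed,
                 paste(names(null@params), unlist(null@params),
                       sep = "=", collapse = " "))
  writeLines(c(hdr, format(null@stats, digits = 17)), file)
  invisible(file)
}

#' @rdname writeNullDistribution
#' @export
readNullDistribution <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- strsplit(hdr, "=")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  new("NullDistribution", mode = unname(vals["mode"]),
      stats = as.numeric(lines[-1]),
      seed = suppressWarnings(as.integer(vals["seed"])),
      params = as.list(vals[setdiff(names(vals), c("mode", "seed"))]))
}
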