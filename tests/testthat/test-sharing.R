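test_that("identical homozygous haplotypes give one spanning shared region", {
  hap <- c(rep(0L, 15), rep(2L, 15))
  gp <- tinyPanel(rbind(hap, hap, rep(1L, 30)))
  roh <- callROH(gp, minSnps = 10)
  sh <- findSharedRegions(roh, gp, minCarriers = 2)
  expect_length(sh, 1L)
  expect_equal(S4Vectors::mcols(sh)$N, 2L)
  expect_equal(S4Vectors::mcols(sh)$iFirst, 1L)
  expect_equal(S4Vectors::mcols(sh)$iLast, 30L)
})

test_that("a single discordant interior marker splits the shared interval", {
  hap1 <- rep(0L, 30)
  hap2 <- rep(0L, 30)
  hap2[16] <- 2L                          # homozygous for the other allele
  gp <- tinyPanel(rbind(hap1, hap2))
  roh <- callROH(gp, minSnps = 5)
  sh <- findSharedRegions(roh, gp, minCarriers = 2, minSnps = 5)
  mc <- S4Vectors::mcols(sh)
  expect_equal(sort(mc$iFirst), c(1L, 17L))
  expect_equal(sort(mc$iLast), c(15L, 30L))
  expect_true(all(mc$N == 2L))
})

test_that("missing genotypes act as wildcards inside shared regions", {
  hap1 <- rep(0L, 30)
  hap2 <- rep(0L, 30)
  hap2[16] <- NA
  gp <- tinyPanel(rbind(hap1, hap2))
  roh <- callROH(gp, minSnps = 5, maxMissing = 2)
  sh <- findSharedRegions(roh, gp, minCarriers = 2)
  expect_equal(S4Vectors::mcols(sh)$iFirst, 1L)
  expect_equal(S4Vectors::mcols(sh)$iLast, 30L)
})

test_that("planted carriers are recovered among many patients", {
  model <- populationModel(nMarkers = 1500, nChrom = 2, seed = 21)
  set.seed(31)
  founder <- sample.int(nrow(model$pool), 1)
  focal <- 700L
  T <- 50L; carriers <- 4L
  g <- matrix(0L, T, 1500)
  planted <- matrix(0L, carriers, 2)
  for (k in seq_len(carriers)) {
    aff <- suppressMessages(makeAffected(model, g = 10, founderHap = founder,
                                         focalMarker = focal))
    g[k, ] <- aff$genotype
    planted[k, ] <- c(aff$iFirst, aff$iLast)
  }
  g[(carriers + 1):T, ] <- genotypes(generatePanel(model, T - carriers)$panel)
  gp <- GenotypePanel(g, model$markers, sprintf("p%02d", 1:T))
  roh <- callROH(gp, minSnps = 25)
  sh <- findSharedRegions(roh, gp, minCarriers = 4, minSnps = 25)
  mc <- S4Vectors::mcols(sh)
  hit <- which(mc$N >= 4 & mc$iFirst <= min(planted[, 2]) &
               mc$iLast >= max(planted[, 1]))
  expect_length(hit, 1L)
  expect_true(all(sprintf("p%02d", 1:4) %in% mc$carriers[[hit]]))
})

test_that("minCarriers = 1 returns each individual's runs among its regions", {
  model <- populationModel(nMarkers = 600, nChrom = 1, seed = 22)
  gp <- generatePanel(model, 8, seed = 11)$panel
  roh <- callROH(gp, minSnps = 10)
  sh <- findSharedRegions(roh, gp, minCarriers = 1, minSnps = 10)
  mc <- S4Vectors::mcols(sh)
  mcr <- S4Vectors::mcols(roh)
  for (r in seq_along(roh)) {
    match <- mc$iFirst == mcr$iFirst[r] & mc$iLast == mcr$iLast[r] &
      vapply(mc$carriers, function(cc) mcr$individual[r] %in% cc, logical(1))
    expect_true(any(match))
  }
})

test_that("hbcM reduces correctly and matches exhaustive enumeration", {
  expect_equal(hbcM(0.25, 1, 1), 0.25)     # N = T = 1: HBC_m = HBC_s
  expect_equal(hbcM(0.3, 0, 5), 1)         # N = 0: certain
  expect_equal(hbcM(0.1, 2, 3), 0.028, tolerance = 1e-12)
  for (T in c(2, 5, 9, 12)) {
    for (p in c(0.01, 0.1, 0.5)) {
      for (N in unique(c(1, 2, (T + 1) %/% 2, T))) {
        expect_equal(hbcM(p, N, T), enumSharingTail(p, N, T),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(hbcM(0.1, 4, 3), "exceed")
  expect_error(hbcM(0, 1, 3), "strictly")
})

test_that("hbcM is monotone in p, T and N", {
  expect_true(all(diff(hbcM(c(.01, .05, .2, .5), 2, 10)) > 0))
  expect_true(all(diff(vapply(c(5, 10, 40), function(T) hbcM(.05, 2, T),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(1:5, function(N) hbcM(.05, N, 10),
                              numeric(1))) < 0))
})

test_that("shared regions are scored on the consensus interval", {
  hap <- rep(0L, 40)
  gp <- tinyPanel(rbind(hap, hap), ids = c("u", "v"))
  ctrl <- tinyPanel(matrix(rbinom(30 * 40, 2, 0.4), 30, 40))
  tab <- suppressWarnings(pairwiseHFTable(ctrl))
  roh <- callROH(gp, minSnps = 10)
  sh <- findSharedRegions(roh, gp, minCarriers = 2)
  sc <- scoreSharedRegions(sh, gp, tab, T = 10)
  mc <- S4Vectors::mcols(sc)
  # both carriers have the same allele vector, so pRep is their common
  # HF^2 over the interval, and hbcM is the 2-of-10 binomial tail
  single <- scoreRegions(callROH(gp, "u", minSnps = 10), gp, tab)
  expect_equal(mc$pRep, S4Vectors::mcols(single)$hbcS, tolerance = 1e-12)
  expect_equal(mc$hbcM, hbcM(mc$pRep, 2, 10), tolerance = 1e-12)
  expect_equal(mc$score, -log10(mc$hbcM))
})

test_that("sib-pair adjustment takes the smaller HF^2 and the IBD factor", {
  adj <- sibpairAdjust(1e-6, 1e-4, N = 1)
  expect_equal(adj$familyStat, 1e-6)
  expect_equal(adj$ibdFactor, 1 / 4)
  expect_equal(sibpairAdjust(numeric(0), numeric(0), N = 0)$ibdFactor, 1)
  expect_equal(sibpairAdjust(c(.1, .2), c(.05, .3), N = 3)$ibdFactor, 1 / 64)
  expect_equal(sibpairAdjust(c(.1, .2), c(.05, .3), N = 3)$familyStat,
               c(.05, .2))
  expect_error(sibpairAdjust(c(.1, .2), .05, N = 1), "two affected")
})
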