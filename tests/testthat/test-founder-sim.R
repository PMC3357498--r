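test_that("zero generations keep the whole founder chromosome", {
  set.seed(1)
  expect_equal(transmitFounderSegment(0, 150, 60), c(0, 150))
  expect_error(transmitFounderSegment(5, 100, 120), "outside")
})

test_that("surviving segment length matches the truncated-exponential mean", {
  # each flank is the minimum of g Exp(1/100 cM) distances, truncated at
  # the chromosome ends: E[min(X, a)] = (100/g) (1 - exp(-g a / 100))
  L <- 200; focal <- 80; reps <- 10000
  for (g in c(10, 40)) {
    set.seed(200 + g)
    lens <- replicate(reps, diff(transmitFounderSegment(g, L, focal)))
    expected <- (100 / g) * (1 - exp(-g * focal / 100)) +
      (100 / g) * (1 - exp(-g * (L - focal) / 100))
    se <- stats::sd(lens) / sqrt(reps)
    expect_lt(abs(mean(lens) - expected), 3 * se)
  }
})

test_that("segment length decreases stochastically with generations", {
  set.seed(77)
  means <- vapply(c(10, 30, 50), function(g)
    mean(replicate(2000, diff(transmitFounderSegment(g, 100, 50)))),
    numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("an affected is homozygous exactly over the planted tract", {
  model <- populationModel(nMarkers = 800, nChrom = 2, seed = 41)
  set.seed(9)
  aff <- suppressMessages(makeAffected(model, g = 10))
  span <- aff$iFirst:aff$iLast
  expect_true(all(aff$genotype[span] %in% c(0L, 2L)))
  expect_equal(aff$genotype[span],
               2L * model$pool[aff$founderHap, span])
  expect_equal(aff$haplotypes[1, span], aff$haplotypes[2, span])
})

test_that("background heterozygosity matches the source population", {
  model <- populationModel(nMarkers = 2000, nChrom = 2, seed = 42)
  ctrl <- generatePanel(model, 60, seed = 2)$panel
  hetCtrl <- mean(genotypes(ctrl) == 1L)
  set.seed(10)
  hets <- replicate(30, {
    aff <- suppressMessages(makeAffected(model, g = 10))
    out <- setdiff(seq_len(2000), aff$iFirst:aff$iLast)
    mean(aff$genotype[out] == 1L)
  })
  se <- sqrt(hetCtrl * (1 - hetCtrl) / (30 * 1500))
  expect_lt(abs(mean(hets) - hetCtrl), 5 * se + 0.01)
})

test_that("simulated studies are bit-reproducible under their seed", {
  model <- populationModel(nMarkers = 400, nChrom = 1, seed = 43)
  s1 <- suppressMessages(simulateStudy(model, 10, 4, 2, g = 10, seed = 5))
  s2 <- suppressMessages(simulateStudy(model, 10, 4, 2, g = 10, seed = 5))
  expect_identical(genotypes(s1$cases), genotypes(s2$cases))
  expect_identical(genotypes(s1$controls), genotypes(s2$controls))
  expect_identical(s1$planted, s2$planted)
  s3 <- suppressMessages(simulateStudy(model, 10, 4, 2, g = 10, seed = 6))
  expect_false(identical(genotypes(s1$cases), genotypes(s3$cases)))
})

test_that("sib-pair simulation plants overlapping tracts in both sibs", {
  model <- populationModel(nMarkers = 1000, nChrom = 1, seed = 44)
  sim <- suppressMessages(
    simulateSibPairs(model, nFamilies = 4, nCarrierFamilies = 2, g = 10,
                     seed = 8, minPlantedSnps = 30))
  gp <- sim$cases
  expect_equal(nIndividuals(gp), 8L)
  expect_equal(length(unique(individuals(gp)$family)), 4L)
  for (fam in sim$carrierFamilies) {
    sibs <- individuals(gp)$id[individuals(gp)$family == fam]
    pl <- sim$planted[sim$planted$id %in% sibs, ]
    expect_equal(nrow(pl), 2L)
    # both sibs homozygous for the founder over their own tracts, which
    # overlap because the parental segments are shared
    expect_lt(max(pl$iFirst), min(pl$iLast))
    for (k in 1:2) {
      span <- pl$iFirst[k]:pl$iLast[k]
      row <- match(pl$id[k], individuals(gp)$id)
      expect_equal(genotypes(gp)[row, span],
                   2L * model$pool[sim$founderHap, span],
                   ignore_attr = TRUE)
    }
  }
})

test_that("sibling sharing probability is one and declines with distance", {
  p0 <- cousinSharingProbability(0, 2, replicates = 200, seed = 1)
  expect_equal(p0$probability, 1)
  p1 <- cousinSharingProbability(1, 2, replicates = 400, seed = 2)
  p3 <- cousinSharingProbability(3, 2, replicates = 400, seed = 3)
  expect_gt(p1$probability, 0.95)          # first cousins nearly always share
  expect_gt(p1$probability, p3$probability)
  # requiring a third relative to share can only lower the probability
  p3b <- cousinSharingProbability(3, 3, replicates = 400, seed = 3)
  expect_gte(p3$probability, p3b$probability)
})

test_that("distant-cousin sharing matches the closed-form expectation", {
  # expected number of segments shared by two k-th cousins from one
  # ancestral couple: about a (r m + c) / 2^(m-1) with a = 2 ancestors,
  # m = 2k + 2 meioses, r the map length in Morgans, c = 22 chromosomes;
  # P(any) ~ that expectation when it is small
  map <- autosomeGeneticMap()
  r <- sum(map$lengthCM) / 100
  k <- 7
  m <- 2 * k + 2
  eSeg <- 2 * (r * m + 22) / 2^(m - 1)   # expected shared segment count
  expected <- 1 - exp(-eSeg)
  sim <- cousinSharingProbability(k, 2, replicates = 4000, seed = 11)
  expect_lt(abs(sim$probability - expected),
            4 * sqrt(expected * (1 - expected) / 4000) + 0.1 * expected)
})
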