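test_that("EM handles unambiguous panels exactly", {
  # all individuals homozygous AB/AB: P_AB = 1
  gp <- tinyPanel(matrix(0L, 6, 2))
  em <- emPairwiseHF(gp, 1, 2)
  expect_equal(unname(em$p), c(1, 0, 0, 0))
  expect_equal(em$v, 6L)
  # no double heterozygotes: the EM fixed point is direct counting
  g <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(2L, 2L), c(0L, 0L),
             c(2L, 1L))
  gp2 <- tinyPanel(g)
  em2 <- emPairwiseHF(gp2, 1, 2)
  # count haplotypes by hand: unambiguous phase throughout
  hapCounts <- c(AB = 2 + 1 + 1 + 2, Ab = 1, aB = 1 + 1, ab = 2 + 1) / 12
  expect_equal(unname(em2$p), unname(hapCounts), tolerance = 1e-9)
})

test_that("EM matches a brute-force likelihood grid search", {
  set.seed(101)
  for (rep in 1:50) {
    pTrue <- as.numeric(stats::rmultinom(1, 40, prob = runif(4, .1, 1))) / 40
    haps <- sample(1:4, 40, replace = TRUE,
                   prob = pmax(pTrue, 0.02))
    h1 <- haps[1:20]; h2 <- haps[21:40]
    codeL <- function(h) ifelse(h <= 2, 0L, 1L)   # 'a' allele indicator
    codeR <- function(h) ifelse(h %% 2 == 0, 1L, 0L)
    g <- cbind(codeL(h1) + codeL(h2), codeR(h1) + codeR(h2))
    gp <- tinyPanel(g)
    em <- emPairwiseHF(gp, 1, 2)
    oracle <- gridMaxTwoLocus(classCounts(g, 1, 2))
    expect_equal(unname(em$p), oracle, tolerance = 1e-6)
  }
})

test_that("the rare-haplotype surrogate K solves its defining equation", {
  expect_equal(rareHaplotypeK(1), 1 - 0.95^(1 / 2), tolerance = 1e-12)
  expect_equal(rareHaplotypeK(112), 2.28962e-4, tolerance = 1e-4)
  # defining criterion: unobserved in 2v haplotypes with probability 95%
  for (v in c(1, 10, 112, 5000))
    expect_equal((1 - rareHaplotypeK(v))^(2 * v), 0.95, tolerance = 1e-12)
  # strictly decreasing, with K * 2v -> -log(0.95)
  v <- c(1, 5, 50, 500, 5e5)
  K <- rareHaplotypeK(v)
  expect_true(all(diff(K) < 0))
  expect_equal(K[5] * 2 * v[5], -log(0.95), tolerance = 1e-3)
  expect_error(rareHaplotypeK(0), "positive")
  # the haplotype-count convention is configurable
  expect_equal(rareHaplotypeK(10, nHaplotypes = 10), 1 - 0.95^(1 / 10))
})

test_that("a two-marker region frequency is the pairwise frequency", {
  g <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(2L, 2L), c(0L, 0L))
  gp <- tinyPanel(g)
  tab <- pairwiseHFTable(gp)
  case <- tinyPanel(rbind(c(0L, 0L)), ids = "case1")
  r <- callROH(case, minSnps = 2)
  sc <- scoreRegions(r, case, tab)
  expect_equal(S4Vectors::mcols(sc)$hf, hfPairs(tab)$pAB[1])
  expect_equal(S4Vectors::mcols(sc)$hbcS,
               S4Vectors::mcols(sc)$hf^2)
})

test_that("without LD the chain reduces to the allele-frequency product", {
  model <- populationModel(nMarkers = 40, nChrom = 1, rho = 0,
                           mode = "markov", seed = 6)
  tab <- trueHFTable(model)
  case <- GenotypePanel(matrix(rep(0L, 40), 1), model$markers, "c1")
  r <- callROH(case, minSnps = 40)
  sc <- scoreRegions(r, case, tab)
  prod0 <- prod(1 - model$pB)     # P(allele A) at every marker
  expect_equal(S4Vectors::mcols(sc)$hf, prod0, tolerance = 1e-9)
})

test_that("region frequency agrees with direct chain evaluation and truth", {
  model <- populationModel(nMarkers = 60, nChrom = 1, mode = "markov",
                           rho = 0.6, seed = 12)
  pop <- generatePanel(model, 1000, seed = 3)
  # the case carries one sampled haplotype homozygous over markers 20..29
  span <- 20:29
  hap <- pop$haplotypes[7, ]
  codes <- rep(1L, 60)
  codes[span] <- 2L * hap[span]
  case <- GenotypePanel(matrix(codes, 1), model$markers, "c1")
  r <- callROH(case, minSnps = 10)
  # oracle route 1: chain evaluated by hand from pairwise tables counted
  # on the phased truth; the package chain on the same counted table
  # must match exactly
  haps <- pop$haplotypes
  li <- 1:59; ri <- 2:60
  cnt <- function(i, x, j, y) colMeans(haps[, i] == x & haps[, j] == y)
  pairs <- data.frame(chrom = "1", i = li, j = ri,
                      pAB = cnt(li, 0, ri, 0), pAb = cnt(li, 0, ri, 1),
                      paB = cnt(li, 1, ri, 0), pab = cnt(li, 1, ri, 1),
                      v = 1000L, K = rareHaplotypeK(1000L),
                      converged = TRUE)
  tabCounted <- rohmap:::buildHFTable(pairs, model$markers$id)
  sc <- scoreRegions(r, case, tabCounted)
  direct <- countedChainHF(haps, hap[span], span)
  expect_equal(S4Vectors::mcols(sc)$hf, direct, tolerance = 1e-10)
  # the estimate is within a small factor of the generator's true HF
  tabTrue <- trueHFTable(model)
  scTrue <- scoreRegions(r, case, tabTrue)
  expect_equal(S4Vectors::mcols(sc)$hf, S4Vectors::mcols(scTrue)$hf,
               tolerance = 0.05)
  chainTrue <- local({
    p <- ifelse(hap[span[1]] == 1, model$pB[span[1]], 1 - model$pB[span[1]])
    acc <- p
    for (k in 2:length(span)) {
      i <- span[k - 1]
      p11 <- model$p11[i]
      joint <- switch(paste0(hap[i], hap[i + 1]),
                      "11" = p11, "10" = model$pB[i] - p11,
                      "01" = model$pB[i + 1] - p11,
                      "00" = 1 - model$pB[i] - model$pB[i + 1] + p11)
      marg <- if (hap[i] == 1) model$pB[i] else 1 - model$pB[i]
      acc <- acc * joint / marg
    }
    acc
  })
  expect_equal(S4Vectors::mcols(scTrue)$hf, chainTrue, tolerance = 1e-12)
})

test_that("log HF is additive over a split at an interior marker", {
  model <- populationModel(nMarkers = 30, nChrom = 1, mode = "markov",
                           seed = 9)
  pop <- generatePanel(model, 80, seed = 4)
  tab <- pairwiseHFTable(pop$panel)
  hap <- pop$haplotypes[1, ]
  mkCase <- function(span) {
    codes <- rep(1L, 30); codes[span] <- 2L * hap[span]
    cp <- GenotypePanel(matrix(codes, 1), model$markers, "c1")
    sc <- scoreRegions(callROH(cp, minSnps = 2), cp, tab)
    S4Vectors::mcols(sc)$logHF
  }
  whole <- mkCase(5:20)
  left <- mkCase(5:12)
  right <- mkCase(12:20)
  # log marginal of the split-point allele, as the chain uses it
  pairAt <- integer(30); pairAt[hfPairs(tab)$i] <- seq_len(nrow(hfPairs(tab)))
  margLog <- tab@logMarg[pairAt[12], 1 + (hap[12] == 1)]
  expect_equal(whole, left + right - margLog, tolerance = 1e-10)
})

test_that("extending a region never increases HF", {
  model <- populationModel(nMarkers = 80, nChrom = 1, seed = 10)
  pop <- generatePanel(model, 50, seed = 5)
  tab <- suppressWarnings(pairwiseHFTable(pop$panel))
  hap <- pop$haplotypes[3, ]
  prev <- Inf
  for (len in c(5, 10, 20, 40, 60)) {
    span <- 10:(10 + len - 1)
    codes <- rep(1L, 80); codes[span] <- 2L * hap[span]
    cp <- GenotypePanel(matrix(codes, 1), model$markers, "c1")
    sc <- scoreRegions(callROH(cp, minSnps = 2), cp, tab)
    cur <- S4Vectors::mcols(sc)$logHF
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("unseen case transitions fall back to K with renormalization", {
  # controls carry only AB and ab haplotypes; the case carries Ab
  g <- rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(2L, 2L), c(0L, 0L))
  gp <- tinyPanel(g)
  tab <- pairwiseHFTable(gp)
  case <- tinyPanel(rbind(c(0L, 2L)), ids = "c1")
  sc <- scoreRegions(callROH(case, minSnps = 2), case, tab)
  K <- rareHaplotypeK(5)
  pAB <- hfPairs(tab)$pAB[1]
  margA <- pAB + hfPairs(tab)$pAb[1]
  expect_equal(S4Vectors::mcols(sc)$hf,
               margA * K / (K + (1 - K) * pAB), tolerance = 1e-12)
})

test_that("HF table round-trips through its TSV cache", {
  model <- populationModel(nMarkers = 50, nChrom = 2, seed = 13)
  pop <- generatePanel(model, 40, seed = 6)
  tab <- pairwiseHFTable(pop$panel)
  f <- tempfile(fileext = ".tsv")
  writeHFTable(tab, f)
  tab2 <- readHFTable(f, pop$panel)
  expect_equal(hfPairs(tab2)$pAB, hfPairs(tab)$pAB, tolerance = 1e-12)
  expect_equal(tab2@logCond, tab@logCond, tolerance = 1e-10)
})

test_that("missing genotypes inside a region are bridged by the chain", {
  model <- populationModel(nMarkers = 30, nChrom = 1, mode = "markov",
                           seed = 14)
  pop <- generatePanel(model, 100, seed = 7)
  tab <- pairwiseHFTable(pop$panel)
  hap <- pop$haplotypes[2, ]
  codes <- rep(1L, 30); codes[5:24] <- 2L * hap[5:24]
  codes[c(12, 17)] <- NA
  cp <- GenotypePanel(matrix(codes, 1), model$markers, "c1")
  r <- callROH(cp, minSnps = 10, maxMissing = 2)
  sc <- scoreRegions(r, cp, tab)
  expect_true(is.finite(S4Vectors::mcols(sc)$logHF))
  # bridging marginalizes: the bridged HF cannot exceed the HF of the
  # same region with the missing markers observed
  codesFull <- rep(1L, 30); codesFull[5:24] <- 2L * hap[5:24]
  cpF <- GenotypePanel(matrix(codesFull, 1), model$markers, "c1")
  scF <- scoreRegions(callROH(cpF, minSnps = 10), cpF, tab)
  expect_gte(S4Vectors::mcols(sc)$logHF, S4Vectors::mcols(scF)$logHF - 1e-9)
})
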