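test_that("PLINK text reader parses a hand-written panel", {
  prefix <- writeTinyPed()
  gp <- readPanel(prefix, format = "plink")
  expect_s4_class(gp, "GenotypePanel")
  expect_equal(dim(genotypes(gp)), c(3L, 4L))
  expect_equal(individuals(gp)$role, c("case", "control", "control"))
  expect_equal(individuals(gp)$family, c("f1", "f2", NA))
  # markers sorted by (chrom, pos); chrom 2 marker last
  expect_equal(markers(gp)$id, c("rs1", "rs2", "rs3", "rs4"))
  # allele A is the first allele observed in the file
  expect_equal(markers(gp)$alleleA[1], "A")
  expect_equal(unname(genotypes(gp)[, "rs1"]), c(0L, 1L, 2L))
  # explicit missing stays missing
  expect_true(is.na(genotypes(gp)["c", "rs3"]))
})

test_that("malformed ped line errors with its line number", {
  prefix <- writeTinyPed()
  lines <- readLines(paste0(prefix, ".ped"))
  lines[2] <- paste(lines[2], "EXTRA")
  writeLines(lines, paste0(prefix, ".ped"))
  expect_error(readPanel(prefix, format = "plink"), "line 2")
})

test_that("VCF reader keeps biallelic sites and warns on the rest", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\tv2\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t300\tv3\tG\tA\t.\tPASS\t.\tGT\t1|1\t./.",
    "1\t400\tv4\tT\tC\t.\tPASS\t.\tGT\t0/1:12\t0/0",
    "2\t100\tv5\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/0"), f)
  expect_warning(gp <- readPanel(f), "non-biallelic")
  expect_equal(nMarkers(gp), 4L)                   # multi-allelic skipped
  expect_equal(unname(genotypes(gp)[, "v3"]), c(2L, NA))
  expect_equal(unname(genotypes(gp)[, "v4"]), c(1L, 0L))  # GT-only parsing
})

test_that("panels round-trip through both dialects", {
  model <- populationModel(nMarkers = 120, nChrom = 2, seed = 8)
  gp <- generatePanel(model, 12, seed = 1, missingRate = 0.02)$panel
  # VCF preserves allele order, so the round trip is exact
  f <- tempfile(fileext = ".vcf")
  writePanel(gp, f, format = "vcf")
  expect_equal(unname(genotypes(readPanel(f))), unname(genotypes(gp)))
  # PLINK: one write/read cycle canonicalizes the per-marker allele
  # order (A = first observed); after that the round trip is exact,
  # and the first cycle changes dosages only by full complement
  d <- tempfile()
  writePanel(gp, d, format = "plink")
  g1 <- readPanel(d)
  flip <- genotypes(g1) != genotypes(gp)
  flippedCols <- apply(flip, 2, any)
  expect_true(all(genotypes(g1)[, flippedCols] ==
                  2L - genotypes(gp)[, flippedCols], na.rm = TRUE))
  d2 <- tempfile()
  writePanel(g1, d2, format = "plink")
  expect_equal(genotypes(readPanel(d2)), genotypes(g1))
})

test_that("marker order is invariant under input row shuffling", {
  prefix <- writeTinyPed()
  mapLines <- readLines(paste0(prefix, ".map"))
  pedLines <- readLines(paste0(prefix, ".ped"))
  gp1 <- readPanel(prefix, format = "plink")
  # shuffle map rows and the corresponding ped allele pairs
  perm <- c(3, 1, 4, 2)
  writeLines(mapLines[perm], paste0(prefix, ".map"))
  shuffled <- vapply(pedLines, function(l) {
    f <- strsplit(l, " ")[[1]]
    al <- matrix(f[-(1:6)], nrow = 2)
    paste(c(f[1:6], as.vector(al[, perm])), collapse = " ")
  }, character(1))
  writeLines(shuffled, paste0(prefix, ".ped"))
  gp2 <- readPanel(prefix, format = "plink")
  expect_equal(markers(gp2)$id, markers(gp1)$id)
  expect_equal(genotypes(gp2), genotypes(gp1))
})

test_that("merging harmonizes swapped alleles and rejects mismatches", {
  g <- rbind(c(0L, 1L, 2L), c(2L, 0L, 0L))
  mk <- data.frame(id = c("m1", "m2", "m3"), chrom = "1",
                   pos = c(100L, 200L, 300L),
                   alleleA = c("A", "C", "A"), alleleB = c("G", "T", "C"))
  x <- GenotypePanel(g, mk, c("a1", "a2"))
  # same markers, m2 with swapped allele labels: dosages must flip back
  mk2 <- mk
  mk2$alleleA[2] <- "T"; mk2$alleleB[2] <- "C"
  y <- GenotypePanel(rbind(c(0L, 2L, 1L)), mk2, "b1")
  m <- mergePanels(x, y)
  expect_equal(nIndividuals(m), 3L)
  expect_equal(unname(genotypes(m)[3, ]), c(0L, 0L, 1L))
  # strand flip (G/A vs C/T) is excluded, not resolved
  mk3 <- mk
  mk3$alleleA[1] <- "T"; mk3$alleleB[1] <- "C"
  z <- GenotypePanel(rbind(c(0L, 1L, 1L)), mk3, "c1")
  expect_warning(m2 <- mergePanels(x, z), "strand")
  expect_equal(nMarkers(m2), 2L)
  # a genuinely different allele set is a hard error
  mk4 <- mk
  mk4$alleleA[3] <- "C"; mk4$alleleB[3] <- "G"
  w <- GenotypePanel(rbind(c(0L, 1L, 1L)), mk4, "d1")
  expect_error(mergePanels(x, w), "mismatch")
})

test_that("region tables and BED exports use the right coordinates", {
  gp <- tinyPanel(rbind(rep(0L, 30)))
  r <- callROH(gp, minSnps = 10)
  f <- tempfile()
  df <- writeRegionTable(r, f)
  expect_equal(df$start_bp, 1000)
  expect_equal(df$end_bp, 30000)
  expect_equal(df$n_snps, 30L)
  expect_true(file.exists(f))
  bed <- regionsAsBed(r, tempfile())
  expect_equal(bed$start, 999)         # 0-based half-open at the boundary
  expect_equal(bed$end, 30000)
})
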