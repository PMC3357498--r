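# Reading and writing genotype panels (PLINK text and VCF dialects),
# harmonization of case/control panels, and region-table export.

#' Read a genotype panel
#'
#' Reads case/control SNP genotypes into a [GenotypePanel]. Two dialects
#' are supported: PLINK text (`.ped`/`.map` pair, pass either file or the
#' common prefix) and VCF (GT field only, via \pkg{vcfR}). Markers are
#' sorted by (chromosome, position). Allele A of each marker is the first
#' allele observed in the file (for VCF, the REF allele); genotypes are
#' stored as allele-B dosages. Non-biallelic sites are skipped with a
#' warning; genotypes are never imputed.
#'
#' @param path file path: `.ped`, `.map` or prefix for PLINK; a `.vcf`
#'   file for VCF.
#' @param format `"plink"` or `"vcf"`; guessed from the extension when
#'   missing.
#' @return a [GenotypePanel]. PLINK phenotype 2 maps to role `"case"`,
#'   anything else to `"control"`; the PLINK family id column fills
#'   `family`.
#' @examples
#' gp <- generatePanel(populationModel(nMarkers = 20, seed = 1), 4)$panel
#' d <- tempfile()
#' writePanel(gp, d, format = "plink")
#' gp2 <- readPanel(d, format = "plink")
#' identical(genotypes(gp), genotypes(gp2))
#' @export
readPanel <- function(path, format = c("plink", "vcf")) {
  if (missing(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  }
  format <- match.arg(format)
  switch(format, plink = readPlinkText(path), vcf = readVcfPanel(path))
}

readPlinkText <- function(path) {
  prefix <- sub("\\.(ped|map)$", "", path)
  pedFile <- paste0(prefix, ".ped")
  mapFile <- paste0(prefix, ".map")
  if (!file.exists(pedFile)) stop("ped file not found: ", pedFile)
  if (!file.exists(mapFile)) stop("map file not found: ", mapFile)

  map <- utils::read.table(mapFile, header = FALSE, colClasses = "character")
  if (ncol(map) != 4) stop("malformed .map: expected 4 columns")
  mk <- data.frame(id = map[[2]], chrom = map[[1]],
                   pos = as.integer(map[[4]]),
                   cM = suppressWarnings(as.numeric(map[[3]])),
                   alleleA = NA_character_, alleleB = NA_character_)
  nm <- nrow(mk)

  lines <- readLines(pedFile)
  lines <- lines[nzchar(trimws(lines))]
  ni <- length(lines)
  fam <- character(ni); id <- character(ni); pheno <- character(ni)
  a1 <- matrix(NA_character_, ni, nm)
  a2 <- matrix(NA_character_, ni, nm)
  for (r in seq_len(ni)) {
    f <- strsplit(trimws(lines[r]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * nm)
      stop("malformed .ped line ", r, ": expected ", 6 + 2 * nm,
           " fields, got ", length(f))
    fam[r] <- f[1]; id[r] <- f[2]; pheno[r] <- f[6]
    al <- f[-(1:6)]
    a1[r, ] <- al[seq(1, 2 * nm, by = 2)]
    a2[r, ] <- al[seq(2, 2 * nm, by = 2)]
  }
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA

  keep <- rep(TRUE, nm)
  g <- matrix(NA_integer_, ni, nm)
  for (m in seq_len(nm)) {
    obs <- c(rbind(a1[, m], a2[, m]))      # file order, first observed = A
    alleles <- unique(obs[!is.na(obs)])
    if (length(alleles) > 2) {
      warning("marker ", mk$id[m], " has ", length(alleles),
              " alleles; skipped")
      keep[m] <- FALSE
      next
    }
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, if (alleles == "B") "b" else "B")
    mk$alleleA[m] <- alleles[1]; mk$alleleB[m] <- alleles[2]
    g[, m] <- (a1[, m] == alleles[2]) + (a2[, m] == alleles[2])
  }
  ind <- data.frame(id = id, role = ifelse(pheno == "2", "case", "control"),
                    family = ifelse(fam %in% c("0", ""), NA_character_, fam))
  GenotypePanel(g[, keep, drop = FALSE], mk[keep, , drop = FALSE], ind)
}

readVcfPanel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  alt <- fix[, "ALT"]
  keep <- !grepl(",", alt) & !is.na(alt)
  if (any(!keep))
    warning(sum(!keep), " non-biallelic site(s) skipped")
  gt <- v@gt[keep, -1, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # GT is the first colon-separated field
  gtOnly <- sub(":.*$", "", gt)
  g1 <- substr(gtOnly, 1, 1)
  g3 <- substr(gtOnly, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ok <- g1 %in% c("0", "1") & g3 %in% c("0", "1")
  dos[ok] <- as.integer(g1[ok]) + as.integer(g3[ok])
  mk <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]), cM = NA_real_,
                   alleleA = fix[, "REF"], alleleB = fix[, "ALT"])
  noid <- is.na(mk$id) | mk$id == "."
  mk$id[noid] <- paste0(mk$chrom[noid], ":", mk$pos[noid])
  GenotypePanel(t(dos), mk, colnames(gt))
}

#' Write a genotype panel
#'
#' Writes a [GenotypePanel] in PLINK text (`prefix.ped` + `prefix.map`)
#' or minimal VCF (GT only) form, the inverse of [readPanel()].
#'
#' @param panel a [GenotypePanel]
#' @param path output prefix (PLINK) or file path (VCF)
#' @param format `"plink"` or `"vcf"`
#' @return invisibly, the path(s) written
#' @export
writePanel <- function(panel, path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  mk <- markers(panel)
  ind <- individuals(panel)
  g <- genotypes(panel)
  if (format == "plink") {
    map <- data.frame(mk$chrom, mk$id,
                      ifelse(is.na(mk$cM), 0, mk$cM), mk$pos)
    utils::write.table(map, paste0(path, ".map"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    nm <- nrow(mk)
    al <- matrix("0", nrow(ind), 2 * nm)
    for (m in seq_len(nm)) {
      code <- g[, m]
      # heterozygotes written alleleA first, so a panel already in the
      # reader's first-observed-is-A coding round-trips identically
      a <- ifelse(is.na(code), "0", ifelse(code == 2, mk$alleleB[m], mk$alleleA[m]))
      b <- ifelse(is.na(code), "0", ifelse(code >= 1, mk$alleleB[m], mk$alleleA[m]))
      al[, 2 * m - 1] <- a
      al[, 2 * m] <- b
    }
    ped <- cbind(ifelse(is.na(ind$family), "0", ind$family), ind$id,
                 "0", "0", "0", ifelse(ind$role == "case", "2", "1"), al)
    utils::write.table(ped, paste0(path, ".ped"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    return(invisible(paste0(path, c(".ped", ".map"))))
  }
  # minimal VCF 4.2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ind$id), collapse = "\t")), con)
  gtStr <- matrix("./.", nrow(g), ncol(g))
  gtStr[!is.na(g) & g == 0] <- "0/0"
  gtStr[!is.na(g) & g == 1] <- "0/1"
  gtStr[!is.na(g) & g == 2] <- "1/1"
  rows <- apply(cbind(mk$chrom, mk$pos, mk$id, mk$alleleA, mk$alleleB,
                      ".", "PASS", ".", "GT", t(gtStr)), 1, paste,
                collapse = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Merge and harmonize case and control panels
#'
#' Restricts both panels to their shared markers (matched by marker id
#' and position) and reconciles allele coding: identical labels pass
#' through, swapped labels flip the dosage of the second panel, apparent
#' strand flips (A/T <-> T/A, C/G complements) are excluded with a
#' warning (strand is never auto-resolved), and any other allele
#' mismatch is an error.
#'
#' @param x,y two [GenotypePanel] objects on overlapping marker maps
#' @return a single [GenotypePanel] containing all individuals of both
#'   panels on the harmonized marker set
#' @export
mergePanels <- function(x, y) {
  mx <- markers(x); my <- markers(y)
  common <- intersect(mx$id, my$id)
  if (!length(common)) stop("no shared markers between panels")
  ix <- match(common, mx$id); iy <- match(common, my$id)
  if (!all(mx$chrom[ix] == my$chrom[iy] & mx$pos[ix] == my$pos[iy]))
    stop("shared marker ids disagree on chromosome/position")
  aA <- mx$alleleA[ix]; aB <- mx$alleleB[ix]
  bA <- my$alleleA[iy]; bB <- my$alleleB[iy]
  same <- aA == bA & aB == bB
  swap <- aA == bB & aB == bA & !same
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flp <- function(z) ifelse(z %in% names(comp), comp[z], z)
  strand <- !same & !swap &
    ((flp(bA) == aA & flp(bB) == aB) | (flp(bA) == aB & flp(bB) == aA))
  bad <- !same & !swap & !strand
  if (any(bad))
    stop("allele mismatch at marker(s): ",
         paste(utils::head(common[bad], 5), collapse = ", "))
  if (any(strand))
    warning(sum(strand), " marker(s) excluded as apparent strand flips")
  keep <- same | swap
  gx <- genotypes(x)[, ix[keep], drop = FALSE]
  gy <- genotypes(y)[, iy[keep], drop = FALSE]
  sw <- swap[keep]
  gy[, sw] <- 2L - gy[, sw]
  GenotypePanel(rbind(gx, gy), mx[ix[keep], , drop = FALSE],
                rbind(individuals(x), individuals(y)))
}

#' Write a region/score table as TSV
#'
#' Exports scored regions (from [callROH()]/[scoreRegions()]/
#' [findSharedRegions()]) in the native 1-based closed-interval TSV
#' layout: chrom, start_bp, end_bp, n_snps, individuals, HF, HBC_s,
#' HBC_m, empirical_P. Columns that were never computed are left as NA.
#'
#' @param regions a `GRanges` of regions with the package's metadata
#'   columns
#' @param file output path
#' @return invisibly, the data.frame written
#' @export
writeRegionTable <- function(regions, file) {
  mc <- S4Vectors::mcols(regions)
  pick <- function(nm) if (nm %in% names(mc)) mc[[nm]] else NA
  carriers <- if ("carriers" %in% names(mc)) {
    vapply(mc$carriers, paste, character(1), collapse = ",")
  } else pick("individual")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start_bp = GenomicRanges::start(regions),
    end_bp = GenomicRanges::end(regions),
    n_snps = pick("nSnps"),
    individuals = carriers,
    HF = pick("hf"),
    HBC_s = pick("hbcS"),
    HBC_m = pick("hbcM"),
    empirical_P = pick("empiricalP"))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export regions as BED
#'
#' Converts the package's 1-based closed intervals to BED's 0-based
#' half-open convention at this boundary only.
#'
#' @inheritParams writeRegionTable
#' @export
regionsAsBed <- function(regions, file) {
  mc <- S4Vectors::mcols(regions)
  name <- if ("individual" %in% names(mc)) mc$individual else "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions),
                   name = name)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(df)
}
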