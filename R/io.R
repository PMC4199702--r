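MISSING_SYMBOL <- "-"

#' Read and write the genotype-matrix CSV dialect
#'
#' The dialect is a rotated marker table in the style of qtl-cross CSV
#' files: the header row holds `id` followed by marker names, the second
#' row the chromosome of each marker (blank under `id`), the third row the
#' 1-based physical position (bp), and each following row one individual.
#' Genotype codes are `A`, `H`, `B` and `-` for missing.
#' `readGenotypeCsv(writeGenotypeCsv(x, p))` reproduces `x` exactly, and
#' canonical files are byte-stable under a write/read/write round trip.
#'
#' @param path File path.
#' @return `readGenotypeCsv()`: a [RilGenotypes-class] object;
#'   `writeGenotypeCsv()`: `path`, invisibly.
#' @export
readGenotypeCsv <- function(path) {
  raw <- read.csv(path, header = FALSE, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) < 3L || ncol(raw) < 2L)
    stop("malformed genotype CSV: need a header, a chromosome row, ",
         "a position row and at least one marker column", call. = FALSE)
  if (tolower(raw[1L, 1L]) != "id")
    stop("malformed genotype CSV: first header field must be 'id'",
         call. = FALSE)
  markers <- as.character(raw[1L, -1L])
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  chrom <- as.character(raw[2L, -1L])
  pos <- suppressWarnings(as.numeric(raw[3L, -1L]))
  if (anyNA(pos))
    stop("malformed genotype CSV: non-numeric physical position",
         call. = FALSE)
  o <- order(match(chrom, unique(chrom)), pos)
  if (!identical(o, seq_along(pos)))
    stop("markers are not sorted by (chromosome, position)", call. = FALSE)
  body <- raw[-(1:3), , drop = FALSE]
  ids <- as.character(body[, 1L])
  g <- as.matrix(body[, -1L, drop = FALSE])
  g[g %in% c(MISSING_SYMBOL, "", "NA")] <- NA_character_
  bad <- which(!is.na(g) & !(g %in% GENO_CODES), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "invalid genotype '%s' for individual '%s' at marker '%s'",
      g[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]], markers[bad[1L, 2L]]),
      call. = FALSE)
  g <- t(g)   # markers x individuals
  dimnames(g) <- list(markers, ids)
  rilGenotypes(g, chrom = chrom, pos = as.integer(pos))
}

#' @param x A [RilGenotypes-class] object.
#' @rdname readGenotypeCsv
#' @export
writeGenotypeCsv <- function(x, path) {
  stopifnot(is(x, "RilGenotypes"))
  info <- markerInfo(x)
  g <- genotypes(x)
  g[is.na(g)] <- MISSING_SYMBOL
  lines <- c(
    paste(c("id", info$marker), collapse = ","),
    paste(c("", info$chrom), collapse = ","),
    paste(c("", info$pos), collapse = ",")
  )
  if (ncol(g))
    lines <- c(lines, vapply(seq_len(ncol(g)), function(i)
      paste(c(colnames(g)[i], g[, i]), collapse = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Import a biparental population from VCF
#'
#' Builds a [RilGenotypes-class] matrix from a VCF 4.x file containing the
#' two parents and their derived individuals.  Sites are retained only if
#' biallelic with the two parents homozygous for different alleles;
#' offspring genotypes are then recoded by parental origin (`A` =
#' homozygous parent 1, `H` = heterozygous, `B` = homozygous parent 2).
#' Calls with genotype quality below `minGq` (or no GQ) are set to
#' missing before site-level completeness is assessed; sites typed in
#' fewer than `minTypedFraction` of the offspring after masking are
#' dropped.
#'
#' @param path VCF file (plain or bgzipped) with `GT` and `GQ` FORMAT
#'   fields.
#' @param parent1,parent2 Sample names of the two parents.
#' @param minGq Genotype-quality threshold; calls below it become missing.
#' @param minTypedFraction Minimum fraction of offspring with a
#'   non-missing call for a site to be kept.
#' @return A [RilGenotypes-class] object over the offspring samples.
#' @export
importVcf <- function(path, parent1, parent2, minGq = 20,
                      minTypedFraction = 0.25) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  samples <- colnames(vcf)
  if (!all(c(parent1, parent2) %in% samples))
    stop("parent sample(s) not found in VCF: ",
         paste(setdiff(c(parent1, parent2), samples), collapse = ", "),
         call. = FALSE)
  gtAll <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtAll))
    stop("VCF has no GT field", call. = FALSE)
  if (!"GQ" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF has no GQ field", call. = FALSE)
  gq <- VariantAnnotation::geno(vcf)$GQ
  gtAll <- gsub("|", "/", gtAll, fixed = TRUE)

  nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  p1 <- gtAll[, parent1]
  p2 <- gtAll[, parent2]
  homCodes <- c("0/0", "1/1")
  keep <- nAlt == 1L & p1 %in% homCodes & p2 %in% homCodes & p1 != p2

  offspring <- setdiff(samples, c(parent1, parent2))
  gt <- gtAll[keep, offspring, drop = FALSE]
  gqo <- gq[keep, offspring, drop = FALSE]
  p1k <- p1[keep]

  code <- matrix(NA_character_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/1", "1/0")] <- "H"
  hom0 <- gt == "0/0"
  hom1 <- gt == "1/1"
  p1is0 <- matrix(p1k == "0/0", nrow(gt), ncol(gt))
  code[hom0 & p1is0] <- "A"
  code[hom0 & !p1is0] <- "B"
  code[hom1 & p1is0] <- "B"
  code[hom1 & !p1is0] <- "A"
  lowGq <- is.na(gqo) | gqo < minGq
  code[lowGq] <- NA_character_

  typed <- rowMeans(!is.na(code))
  keep2 <- typed >= minTypedFraction
  code <- code[keep2, , drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(vcf)[keep][keep2]
  if (nrow(code) == 0L)
    stop("no sites pass the parental and completeness filters",
         call. = FALSE)
  rilGenotypes(code,
               chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr))
}
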