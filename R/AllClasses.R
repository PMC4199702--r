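#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Heterozygosity model for a selfed RIL population
#'
#' Bundles the two population-level parameters of the excess-heterozygosity
#' model: the selfing generation `t` (F1 = 1) and the per-generation
#' proportion of heterozygosity maintained, `h` (0.5 under Mendelian
#' segregation).  The locus-pair quantities `u` and `d` depend on the
#' recombination fraction and are derived on demand by [solveViability()].
#'
#' @slot t integer(1); selfing generation interval, >= 1.
#' @slot h numeric(1); per-generation heterozygosity retention in (0, 1).
#' @aliases HetModel
#' @seealso [hetModel()], [hetModelFromH()]
#' @exportClass HetModel
setClass("HetModel", representation(t = "integer", h = "numeric"))

setValidity("HetModel", function(object) {
  msg <- character()
  if (length(object@t) != 1L || is.na(object@t) || object@t < 1L)
    msg <- c(msg, "'t' must be a single integer >= 1")
  if (length(object@h) != 1L || is.na(object@h) ||
      object@h <= 0 || object@h >= 1)
    msg <- c(msg, "'h' must be a single value in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a heterozygosity model
#'
#' @param t Selfing generation interval (integer >= 1; F1 = 1).
#' @param h Per-generation heterozygosity retention in (0, 1);
#'   0.5 is Mendelian.
#' @return A [HetModel-class] object.
#' @examples
#' hetModel(7, 0.6373)
#' hetModelFromH(0.067, 7)    # same model, parameterized from observed H
#' @export
hetModel <- function(t, h = 0.5) {
  t <- .check_t(t, min = 1L)
  new("HetModel", t = t, h = as.numeric(h))
}

#' @param H Observed heterozygous-genotype proportion at generation `t`.
#' @rdname hetModel
#' @export
hetModelFromH <- function(H, t) hetModel(t, hFromH(H, t))

#' @describeIn hetModel Selfing generation of a model.
#' @param object,x A `HetModel`.
#' @export
setGeneric("generation", function(x) standardGeneric("generation"))

#' @rdname hetModel
#' @export
setMethod("generation", "HetModel", function(x) x@t)

#' @describeIn hetModel Per-generation heterozygosity retention `h`.
#' @export
setGeneric("hetRetention", function(x) standardGeneric("hetRetention"))

#' @rdname hetModel
#' @export
setMethod("hetRetention", "HetModel", function(x) x@h)

setMethod("show", "HetModel", function(object) {
  cat("HetModel: selfed F", object@t, " population\n", sep = "")
  cat("  h (heterozygosity retained/generation): ",
      format(object@h, digits = 6), "\n", sep = "")
  cat("  expected heterozygosity H = h^(t-1):     ",
      format(object@h^(object@t - 1L), digits = 6), "\n", sep = "")
  invisible(NULL)
})

#' Genotype matrix for a biparental selfed RIL population
#'
#' `RilGenotypes` extends `RangedSummarizedExperiment`.  The single assay,
#' `"geno"`, is a character matrix of markers (rows) by individuals
#' (columns) with genotype codes `"A"` (homozygous parent 1), `"H"`
#' (heterozygous), `"B"` (homozygous parent 2) and `NA` (missing).
#' Row ranges carry the chromosome and 1-based physical position of each
#' marker; markers are kept sorted by (chromosome, position).
#' Quality-control steps append [QcReport-class] records to
#' `metadata(x)$qcReports` (see [qcReports()]).
#'
#' @aliases RilGenotypes
#' @seealso [rilGenotypes()], [genotypes()], [markerInfo()]
#' @exportClass RilGenotypes
setClass("RilGenotypes", contains = "RangedSummarizedExperiment")

setValidity("RilGenotypes", function(object) {
  msg <- character()
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    return("assay 'geno' is required")
  g <- SummarizedExperiment::assay(object, "geno")
  if (!is.character(g))
    msg <- c(msg, "assay 'geno' must be a character matrix")
  else {
    bad <- !is.na(g) & !(g %in% GENO_CODES)
    if (any(bad))
      msg <- c(msg, sprintf(
        "invalid genotype code(s): %s (allowed: A, H, B, NA)",
        paste(unique(g[bad])[seq_len(min(3L, length(unique(g[bad]))))],
              collapse = ", ")))
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "marker names must be present and unique")
  if (nrow(object) > 1L) {
    chrom <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(object)))
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(object))
    o <- order(match(chrom, unique(chrom)), pos)
    if (!identical(o, seq_len(nrow(object))))
      msg <- c(msg, "markers must be sorted by (chromosome, position)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an RilGenotypes object
#'
#' @param geno Character matrix of genotype codes (`"A"`, `"H"`, `"B"`,
#'   `NA`), markers in rows, individuals in columns.  Row and column
#'   names supply marker and individual identifiers (defaults are
#'   generated when absent).
#' @param chrom Chromosome of each marker (recycled if length 1).
#' @param pos 1-based physical position (bp) of each marker.
#' @return A [RilGenotypes-class] object with markers sorted by
#'   (chromosome, position).
#' @examples
#' g <- matrix(c("A", "H", "B", "A"), nrow = 2,
#'             dimnames = list(c("m1", "m2"), c("i1", "i2")))
#' rilGenotypes(g, chrom = "1", pos = c(100L, 200L))
#' @export
rilGenotypes <- function(geno, chrom, pos) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "character"
  nm <- nrow(geno)
  if (length(chrom) == 1L) chrom <- rep(chrom, nm)
  if (length(chrom) != nm || length(pos) != nm)
    stop("'chrom' and 'pos' must have one entry per marker", call. = FALSE)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("M%04d", seq_len(nm))
  if (is.null(colnames(geno)) && ncol(geno) > 0L)
    colnames(geno) <- sprintf("I%04d", seq_len(ncol(geno)))
  o <- order(match(as.character(chrom), unique(as.character(chrom))), pos)
  geno <- geno[o, , drop = FALSE]
  chrom <- as.character(chrom)[o]
  pos <- as.integer(pos)[o]
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  names(rr) <- rownames(geno)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno), rowRanges = rr)
  new("RilGenotypes", se)
}

#' Accessors for RilGenotypes
#'
#' `genotypes()` returns the marker-by-individual genotype matrix,
#' `markerInfo()` a data frame of marker, chromosome and physical
#' position, and `qcReports()` the list of [QcReport-class] records
#' accumulated by quality-control steps.
#'
#' @param x A [RilGenotypes-class] object.
#' @return See the individual descriptions.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname genotypes
#' @export
setMethod("genotypes", "RilGenotypes",
          function(x) SummarizedExperiment::assay(x, "geno"))

#' @rdname genotypes
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname genotypes
#' @export
setMethod("markerInfo", "RilGenotypes", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(marker = rownames(x),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname genotypes
#' @export
setGeneric("qcReports", function(x) standardGeneric("qcReports"))

#' @rdname genotypes
#' @export
setMethod("qcReports", "RilGenotypes", function(x) {
  reps <- S4Vectors::metadata(x)$qcReports
  if (is.null(reps)) list() else reps
})

setMethod("show", "RilGenotypes", function(object) {
  g <- genotypes(object)
  nchr <- length(unique(as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(object)))))
  cat("RilGenotypes: ", nrow(object), " markers x ", ncol(object),
      " individuals on ", nchr, " chromosome(s)\n", sep = "")
  if (length(g)) {
    cat(sprintf("  missing: %.1f%%   heterozygous: %.1f%% of calls\n",
                100 * mean(is.na(g)),
                100 * mean(g == "H", na.rm = TRUE)))
  }
  nq <- length(qcReports(object))
  if (nq) cat("  qcReports: ", nq, " step(s) recorded\n", sep = "")
  invisible(NULL)
})

#' Quality-control report for one filtering step
#'
#' An audit record attached to [RilGenotypes-class] objects by the QC
#' filters: which individuals and markers a step removed (with reason
#' codes), how many genotype calls it masked, and the population
#' heterozygosity before and after.
#'
#' @slot step character(1); name of the QC step.
#' @slot removedIndividuals data.frame with columns `id`, `reason`.
#' @slot removedMarkers data.frame with columns `marker`, `reason`.
#' @slot maskedGenotypes integer(1); number of calls set to missing.
#' @slot HBefore,HAfter numeric(1); heterozygous proportion before/after.
#' @slot params list; parameters the step was run with.
#' @aliases QcReport
#' @exportClass QcReport
setClass("QcReport", representation(
  step = "character",
  removedIndividuals = "data.frame",
  removedMarkers = "data.frame",
  maskedGenotypes = "integer",
  HBefore = "numeric",
  HAfter = "numeric",
  params = "list"
))

.qcReport <- function(step, removedIndividuals = character(),
                      indReason = character(),
                      removedMarkers = character(),
                      markerReason = character(),
                      maskedGenotypes = 0L,
                      HBefore = NA_real_, HAfter = NA_real_,
                      params = list()) {
  if (length(indReason) == 1L)
    indReason <- rep(indReason, length(removedIndividuals))
  if (length(markerReason) == 1L)
    markerReason <- rep(markerReason, length(removedMarkers))
  new("QcReport", step = step,
      removedIndividuals = data.frame(id = as.character(removedIndividuals),
                                      reason = as.character(indReason),
                                      stringsAsFactors = FALSE),
      removedMarkers = data.frame(marker = as.character(removedMarkers),
                                  reason = as.character(markerReason),
                                  stringsAsFactors = FALSE),
      maskedGenotypes = as.integer(maskedGenotypes),
      HBefore = HBefore, HAfter = HAfter, params = params)
}

setMethod("show", "QcReport", function(object) {
  cat("QcReport [", object@step, "]\n", sep = "")
  cat("  individuals removed: ", nrow(object@removedIndividuals),
      "   markers removed: ", nrow(object@removedMarkers),
      "   genotypes masked: ", object@maskedGenotypes, "\n", sep = "")
  if (!is.na(object@HBefore) || !is.na(object@HAfter))
    cat(sprintf("  H before: %s   H after: %s\n",
                format(object@HBefore, digits = 4),
                format(object@HAfter, digits = 4)))
  invisible(NULL)
})

.appendQcReport <- function(x, report) {
  md <- S4Vectors::metadata(x)
  md$qcReports <- c(md$qcReports, list(report))
  S4Vectors::metadata(x) <- md
  x
}

#' Serialize QC reports to tab-delimited text
#'
#' Writes one row per removed individual, removed marker or masking event
#' for every QC step recorded on `x`.
#'
#' @param x A [RilGenotypes-class] object carrying QC reports.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeQcReports <- function(x, path) {
  reps <- qcReports(x)
  rows <- do.call(rbind, lapply(reps, function(r) {
    out <- data.frame(step = character(), type = character(),
                      item = character(), reason = character(),
                      stringsAsFactors = FALSE)
    if (nrow(r@removedIndividuals))
      out <- rbind(out, data.frame(step = r@step, type = "individual",
                                   item = r@removedIndividuals$id,
                                   reason = r@removedIndividuals$reason))
    if (nrow(r@removedMarkers))
      out <- rbind(out, data.frame(step = r@step, type = "marker",
                                   item = r@removedMarkers$marker,
                                   reason = r@removedMarkers$reason))
    if (r@maskedGenotypes > 0L)
      out <- rbind(out, data.frame(step = r@step, type = "genotype",
                                   item = as.character(r@maskedGenotypes),
                                   reason = "masked_to_missing"))
    out
  }))
  if (is.null(rows))
    rows <- data.frame(step = character(), type = character(),
                       item = character(), reason = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
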