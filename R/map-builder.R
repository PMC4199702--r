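#' Build a genetic map from adjacent-pair recombination estimates
#'
#' Accumulates Haldane distances along each chromosome: the first marker
#' of a chromosome sits at 0 cM and marker `k+1` at
#' `cM[k] + haldaneCM(rf[k])`.  An estimate at the unlinked boundary
#' (`rf >= 0.5 - tol`) gives an infinite distance; the pair is flagged
#' rather than silently propagated, and downstream positions on that
#' chromosome become `Inf`.  Pairs with `rf = NA` (no informative data)
#' are likewise flagged and treated as infinite.
#'
#' @param scan Data frame from [adjacentRfScan()] (ordered,
#'   chromosome-partitioned adjacent-pair estimates).
#' @param boundaryTol Estimates within this distance of 0.5 are treated
#'   as unlinked.
#' @return A data frame with columns `marker`, `chrom`, `pos` (bp) and
#'   `cM`; its `"flaggedPairs"` attribute lists unlinked or uninformative
#'   pairs.  Empty input gives an empty map.
#' @examples
#' sc <- data.frame(chrom = "1", marker1 = "m1", marker2 = "m2",
#'                  pos1 = 1L, pos2 = 1000L, n = 100L, rf = 0.1,
#'                  loglik = -100)
#' buildMap(sc)   # chromosome length 11.157 cM
#' @export
buildMap <- function(scan, boundaryTol = 1e-4) {
  cols <- c("chrom", "marker1", "marker2", "pos1", "pos2", "rf")
  if (nrow(scan) == 0L)
    return(structure(data.frame(marker = character(), chrom = character(),
                                pos = integer(), cM = numeric(),
                                stringsAsFactors = FALSE),
                     flaggedPairs = data.frame()))
  if (!all(cols %in% names(scan)))
    stop("'scan' must contain columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  flagged <- is.na(scan$rf) | scan$rf >= 0.5 - boundaryTol
  maps <- lapply(unique(scan$chrom), function(cc) {
    s <- scan[scan$chrom == cc, , drop = FALSE]
    d <- ifelse(is.na(s$rf) | s$rf >= 0.5 - boundaryTol, Inf,
                haldaneCM(s$rf))
    data.frame(marker = c(s$marker1[1L], s$marker2),
               chrom = cc,
               pos = c(s$pos1[1L], s$pos2),
               cM = c(0, cumsum(d)),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  structure(map, flaggedPairs = scan[flagged, , drop = FALSE])
}

#' Per-chromosome and total map lengths
#'
#' @param map Data frame from [buildMap()].
#' @return A list with `perChromosome` (named vector of chromosome lengths
#'   in cM) and `total`.
#' @export
mapLengths <- function(map) {
  if (nrow(map) == 0L)
    return(list(perChromosome = numeric(), total = 0))
  per <- vapply(split(map$cM, factor(map$chrom, levels = unique(map$chrom))),
                function(cm) max(cm) - min(cm), numeric(1))
  list(perChromosome = per, total = sum(per))
}

#' Compare two genetic maps of the same markers
#'
#' Reports, per chromosome and in total, how much shorter (or longer)
#' `mapB` is than `mapA`: the difference in cM, as a percentage of
#' `mapA`'s length, and as recombinations per meiosis using the reporting
#' convention that 50 cM corresponds to one recombination per meiosis.
#'
#' @param mapA,mapB Data frames from [buildMap()] over identical markers.
#' @return A data frame with rows per chromosome plus a `"total"` row and
#'   columns `chrom`, `lengthA`, `lengthB`, `deltaCM`, `deltaPct`,
#'   `deltaRecombinations`.
#' @examples
#' a <- data.frame(marker = c("m1", "m2"), chrom = "1",
#'                 pos = c(1L, 2L), cM = c(0, 1603.8))
#' b <- data.frame(marker = c("m1", "m2"), chrom = "1",
#'                 pos = c(1L, 2L), cM = c(0, 1390.6))
#' compareMaps(a, b)   # 213.2 cM, ~13%, 4.26 recombinations
#' @export
compareMaps <- function(mapA, mapB) {
  if (!identical(sort(mapA$marker), sort(mapB$marker)))
    stop("maps must cover the same markers", call. = FALSE)
  la <- mapLengths(mapA)
  lb <- mapLengths(mapB)
  chroms <- names(la$perChromosome)
  if (!identical(sort(chroms), sort(names(lb$perChromosome))))
    stop("maps must cover the same chromosomes", call. = FALSE)
  a <- c(la$perChromosome[chroms], total = la$total)
  b <- c(lb$perChromosome[chroms], total = lb$total)
  delta <- a - b
  data.frame(chrom = c(chroms, "total"),
             lengthA = as.numeric(a),
             lengthB = as.numeric(b),
             deltaCM = as.numeric(delta),
             deltaPct = as.numeric(100 * delta / a),
             deltaRecombinations = as.numeric(delta / 50),
             stringsAsFactors = FALSE)
}

#' Write a genetic map to tab-delimited text
#'
#' @param map Data frame from [buildMap()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMap <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Side-by-side summary of map lengths per chromosome
#'
#' Produces a chromosome-by-method table of map lengths (one column per
#' supplied map), a convenient layout for comparing a Mendelian fit with
#' an excess-heterozygosity fit.
#'
#' @param ... Named map data frames from [buildMap()].
#' @return A data frame with a `chrom` column, one length column per map,
#'   and a final `"total"` row.
#' @export
mapSummaryTable <- function(...) {
  maps <- list(...)
  if (!length(maps) || is.null(names(maps)) || any(names(maps) == ""))
    stop("supply named maps, e.g. mapSummaryTable(mendelian = m1, ...)",
         call. = FALSE)
  lens <- lapply(maps, mapLengths)
  chroms <- names(lens[[1L]]$perChromosome)
  out <- data.frame(chrom = c(chroms, "total"), stringsAsFactors = FALSE)
  for (nm in names(lens))
    out[[nm]] <- c(as.numeric(lens[[nm]]$perChromosome[chroms]),
                   lens[[nm]]$total)
  out
}
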