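#' Population heterozygosity
#'
#' Proportion of heterozygous calls among all non-missing genotype calls,
#' overall or per chromosome (one estimate per linkage group).
#'
#' @param x A [RilGenotypes-class] object.
#' @param byChromosome If `TRUE`, return a named vector with one estimate
#'   per chromosome.
#' @return A proportion in [0, 1], or a named vector of proportions.
#' @export
estimateH <- function(x, byChromosome = FALSE) {
  stopifnot(is(x, "RilGenotypes"))
  g <- genotypes(x)
  if (length(g) == 0L || all(is.na(g)))
    stop("cannot estimate H: no non-missing genotype calls", call. = FALSE)
  if (!byChromosome) return(mean(g == "H", na.rm = TRUE))
  chrom <- markerInfo(x)$chrom
  vapply(split(seq_len(nrow(g)), factor(chrom, levels = unique(chrom))),
         function(idx) mean(g[idx, , drop = FALSE] == "H", na.rm = TRUE),
         numeric(1))
}

#' Segregation-distortion test at one marker
#'
#' Chi-square goodness-of-fit test of observed genotype counts against the
#' expected ratio `(1 - H) / 2 : H : (1 - H) / 2` under population
#' heterozygosity `H` (the non-Mendelian null; `H = 0.5` recovers the
#' textbook 1:2:1 test).  The p-value is computed on the log scale so
#' thresholds far below machine underflow remain meaningful.
#'
#' @param nA,nH,nB Genotype counts at the marker.
#' @param Hnull Expected heterozygous proportion under the null, in (0, 1).
#' @param log.p If `TRUE`, return the natural log of the p-value.
#' @return The (upper-tail, df = 2) p-value, or its log.
#' @examples
#' distortionTest(463, 74, 463, Hnull = 0.074)  # exactly the null: p = 1
#' @export
distortionTest <- function(nA, nH, nB, Hnull, log.p = FALSE) {
  n <- nA + nH + nB
  if (is.na(n) || n < 1) stop("zero genotype counts", call. = FALSE)
  if (Hnull <= 0 || Hnull >= 1)
    stop("'Hnull' must be in (0, 1)", call. = FALSE)
  expp <- c((1 - Hnull) / 2, Hnull, (1 - Hnull) / 2)
  expd <- n * expp
  stat <- sum((c(nA, nH, nB) - expd)^2 / expd)
  lp <- pchisq(stat, df = 2, lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

#' Remove markers with segregation distortion
#'
#' Tests every marker with [distortionTest()] against `Hnull` and removes
#' markers with `p < alpha`.  Per-chromosome overrides relax (or tighten)
#' the threshold for named chromosomes, as when one chromosome carries a
#' known selected region.
#'
#' @param x A [RilGenotypes-class] object.
#' @param Hnull Heterozygous proportion of the null ratio.
#' @param alpha Default exclusion threshold on the p-value.
#' @param overrides Named numeric vector or list of per-chromosome alpha
#'   values, e.g. `c("1" = 1e-30)`.
#' @return The filtered object, with a [QcReport-class] appended.
#' @export
filterMarkersByDistortion <- function(x, Hnull, alpha = 1e-15,
                                      overrides = NULL) {
  stopifnot(is(x, "RilGenotypes"))
  g <- genotypes(x)
  info <- markerInfo(x)
  HBefore <- mean(g == "H", na.rm = TRUE)
  nA <- rowSums(g == "A", na.rm = TRUE)
  nH <- rowSums(g == "H", na.rm = TRUE)
  nB <- rowSums(g == "B", na.rm = TRUE)
  tot <- nA + nH + nB
  logp <- rep(0, nrow(g))
  ok <- tot >= 1
  logp[ok] <- mapply(function(a, h, b) distortionTest(a, h, b, Hnull,
                                                      log.p = TRUE),
                     nA[ok], nH[ok], nB[ok])
  thr <- rep(log(alpha), nrow(g))
  if (!is.null(overrides)) {
    ov <- unlist(overrides)
    hit <- info$chrom %in% names(ov)
    thr[hit] <- log(ov[info$chrom[hit]])
  }
  drop <- ok & (logp < thr)   # alpha = 0 -> log(0) = -Inf -> none removed
  out <- x[!drop, ]
  gAfter <- genotypes(out)
  HAfter <- if (length(gAfter) && !all(is.na(gAfter)))
    mean(gAfter == "H", na.rm = TRUE) else NA_real_
  rep <- .qcReport("distortion", removedMarkers = info$marker[drop],
                   markerReason = "segregation_distortion",
                   HBefore = HBefore, HAfter = HAfter,
                   params = list(Hnull = Hnull, alpha = alpha,
                                 overrides = overrides))
  .appendQcReport(out, rep)
}

#' Remove markers and individuals with high missingness
#'
#' Markers at or above `maxMarkerMissing` missing-call fraction are removed
#' first; individuals are then judged against `maxIndividualMissing` on the
#' remaining markers.
#'
#' @param x A [RilGenotypes-class] object.
#' @param maxMarkerMissing,maxIndividualMissing Removal thresholds in
#'   [0, 1]; a fraction equal to the threshold is removed (`>=`).
#' @return The filtered object, with a [QcReport-class] appended.
#' @export
filterMissingness <- function(x, maxMarkerMissing = 0.60,
                              maxIndividualMissing = 0.60) {
  stopifnot(is(x, "RilGenotypes"))
  if (maxMarkerMissing < 0 || maxMarkerMissing > 1 ||
      maxIndividualMissing < 0 || maxIndividualMissing > 1)
    stop("missingness thresholds must be in [0, 1]", call. = FALSE)
  g <- genotypes(x)
  HBefore <- if (length(g) && !all(is.na(g)))
    mean(g == "H", na.rm = TRUE) else NA_real_
  mMiss <- rowMeans(is.na(g))
  dropM <- mMiss >= maxMarkerMissing
  g2 <- g[!dropM, , drop = FALSE]
  iMiss <- if (nrow(g2)) colMeans(is.na(g2)) else rep(0, ncol(g2))
  dropI <- iMiss >= maxIndividualMissing
  out <- x[!dropM, !dropI]
  gAfter <- genotypes(out)
  HAfter <- if (length(gAfter) && !all(is.na(gAfter)))
    mean(gAfter == "H", na.rm = TRUE) else NA_real_
  rep <- .qcReport("missingness",
                   removedIndividuals = colnames(g)[dropI],
                   indReason = "high_missingness",
                   removedMarkers = rownames(g)[dropM],
                   markerReason = "high_missingness",
                   HBefore = HBefore, HAfter = HAfter,
                   params = list(maxMarkerMissing = maxMarkerMissing,
                                 maxIndividualMissing = maxIndividualMissing))
  .appendQcReport(out, rep)
}

# Pairwise genotype concordance over mutually non-missing markers.
.concordance <- function(g) {
  obs <- !is.na(g)
  nShared <- crossprod(obs)                 # individuals x individuals
  nMatch <- matrix(0, ncol(g), ncol(g))
  for (code in GENO_CODES) {
    m <- (g == code) & obs
    storage.mode(m) <- "numeric"
    nMatch <- nMatch + crossprod(m)
  }
  share <- nMatch / nShared
  share[nShared == 0] <- 0
  dimnames(share) <- list(colnames(g), colnames(g))
  share
}

#' Remove near-duplicate individuals
#'
#' Computes pairwise genotype concordance over mutually non-missing
#' markers, links individuals sharing at least `minShare`, and keeps one
#' representative per connected component: the individual with the least
#' missingness, ties broken by input order.
#'
#' @param x A [RilGenotypes-class] object.
#' @param minShare Concordance at or above which two individuals are
#'   considered duplicates.
#' @return The filtered object, with a [QcReport-class] appended.
#' @export
dropDuplicateIndividuals <- function(x, minShare = 0.90) {
  stopifnot(is(x, "RilGenotypes"))
  g <- genotypes(x)
  n <- ncol(g)
  if (n < 2L) return(.appendQcReport(x, .qcReport("duplicates",
                                                  params = list(minShare = minShare))))
  share <- .concordance(g)
  adj <- share >= minShare
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  miss <- colMeans(is.na(g))
  drop <- logical(n)
  for (k in unique(comp)) {
    members <- which(comp == k)
    if (length(members) > 1L) {
      keep <- members[which.min(miss[members])]  # which.min: first on ties
      drop[setdiff(members, keep)] <- TRUE
    }
  }
  out <- x[, !drop]
  rep <- .qcReport("duplicates",
                   removedIndividuals = colnames(g)[drop],
                   indReason = "duplicate_individual",
                   params = list(minShare = minShare))
  .appendQcReport(out, rep)
}

# Mask tight double recombinants in one genotype vector given positions.
# Returns indices (into the vector) to set missing.
.tightDoubleIdx <- function(geno, pos, window) {
  obs <- which(!is.na(geno))
  if (length(obs) < 3L) return(integer())
  v <- geno[obs]
  rl <- rle(v)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  mask <- integer()
  if (length(rl$values) < 3L) return(mask)
  for (j in 2L:(length(rl$values) - 1L)) {
    if (rl$values[j - 1L] != rl$values[j + 1L]) next
    if (rl$values[j] == rl$values[j - 1L]) next
    leftPos <- pos[obs[ends[j - 1L]]]    # nearest non-missing flank calls
    rightPos <- pos[obs[starts[j + 1L]]]
    if (rightPos - leftPos <= window)
      mask <- c(mask, obs[starts[j]:ends[j]])
  }
  mask
}

#' Mask tight double recombinations
#'
#' A run of identical genotype calls flanked on both sides by a different,
#' shared genotype call within a short distance is far more likely to be a
#' genotyping error than two real crossovers; such interior runs are set
#' to missing.  Distance is measured flank-to-flank between the nearest
#' non-missing calls on either side of the run (missing calls are
#' transparent), in base pairs or, given a genetic map, in centimorgans.
#' Runs at chromosome ends are never masked.  Decisions are taken on a
#' snapshot of the input, so the operation is idempotent.
#'
#' @param x A [RilGenotypes-class] object.
#' @param window Maximum flank-to-flank span for masking (bp or cM).
#' @param units `"bp"` (physical positions) or `"cM"` (requires `map`).
#' @param map For `units = "cM"`: a data frame from [buildMap()] with
#'   columns `marker` and `cM` covering the markers of `x`.
#' @return The object with masked calls set to `NA` and a
#'   [QcReport-class] appended.  Masking never turns a call into a
#'   different non-missing call.
#' @export
maskTightDoubleRecombinants <- function(x, window, units = c("bp", "cM"),
                                        map = NULL) {
  stopifnot(is(x, "RilGenotypes"))
  units <- match.arg(units)
  info <- markerInfo(x)
  if (units == "cM") {
    if (is.null(map))
      stop("units = 'cM' requires a genetic map", call. = FALSE)
    mpos <- map$cM[match(info$marker, map$marker)]
    if (anyNA(mpos))
      stop("genetic map does not cover all markers", call. = FALSE)
    pos <- mpos
  } else {
    pos <- info$pos
  }
  g <- genotypes(x)
  masked <- 0L
  for (cc in unique(info$chrom)) {
    idx <- which(info$chrom == cc)
    if (length(idx) < 3L) next
    for (i in seq_len(ncol(g))) {
      mk <- .tightDoubleIdx(g[idx, i], pos[idx], window)
      if (length(mk)) {
        g[idx[mk], i] <- NA_character_
        masked <- masked + length(mk)
      }
    }
  }
  out <- x
  SummarizedExperiment::assay(out, "geno") <- g
  rep <- .qcReport("tight_double_recombination",
                   maskedGenotypes = masked,
                   params = list(window = window, units = units))
  .appendQcReport(out, rep)
}

#' Flag individuals with outlying genotype proportions
#'
#' Computes each individual's fraction of `A`, `H` and `B` calls among its
#' non-missing genotypes and flags individuals falling outside
#' `k` interquartile ranges from the quartiles on any of the three
#' proportions.  Removal is opt-in.
#'
#' @param x A [RilGenotypes-class] object.
#' @param k IQR multiplier (`Inf` flags nothing).
#' @param remove If `TRUE`, drop flagged individuals; otherwise return `x`
#'   unchanged apart from the report.
#' @return The (possibly filtered) object with a [QcReport-class]
#'   appended; the report's `params$flagged` lists flagged individuals.
#' @export
flagOutlierIndividuals <- function(x, k = 3, remove = FALSE) {
  stopifnot(is(x, "RilGenotypes"))
  g <- genotypes(x)
  nObs <- colSums(!is.na(g))
  flagged <- logical(ncol(g))
  if (is.finite(k) && ncol(g) > 0L) {
    for (code in GENO_CODES) {
      frac <- colSums(g == code, na.rm = TRUE) / pmax(nObs, 1L)
      q <- quantile(frac, c(0.25, 0.75), names = FALSE)
      iqr <- q[2L] - q[1L]
      flagged <- flagged | frac < q[1L] - k * iqr | frac > q[2L] + k * iqr
    }
  }
  ids <- colnames(g)[flagged]
  out <- if (remove) x[, !flagged] else x
  rep <- .qcReport("outlier_individuals",
                   removedIndividuals = if (remove) ids else character(),
                   indReason = "outlying_genotype_proportions",
                   params = list(k = k, flagged = ids, remove = remove))
  .appendQcReport(out, rep)
}

#' Iterative segregation-distortion filtering
#'
#' Two-pass (or more) distortion screen with re-estimated heterozygosity:
#' the population heterozygosity `H` is estimated, markers failing
#' [distortionTest()] at that null are removed, `H` is re-estimated on the
#' survivors, and the test is re-applied to the *original* marker set with
#' the updated null.  The retained set therefore reflects the final, less
#' distortion-biased `H`.
#'
#' @param x A [RilGenotypes-class] object.
#' @param alpha,overrides As in [filterMarkersByDistortion()].
#' @param passes Number of filter passes (>= 1).
#' @return The filtered object; `metadata()$Hhistory` records the `H`
#'   estimate used at each pass.
#' @export
iterativeDistortionFilter <- function(x, alpha = 1e-15, overrides = NULL,
                                      passes = 2L) {
  stopifnot(is(x, "RilGenotypes"), passes >= 1L)
  H <- estimateH(x)
  Hhist <- H
  out <- x
  for (pass in seq_len(passes)) {
    out <- filterMarkersByDistortion(x, Hnull = H, alpha = alpha,
                                     overrides = overrides)
    H <- estimateH(out)
    Hhist <- c(Hhist, H)
  }
  md <- S4Vectors::metadata(out)
  md$Hhistory <- Hhist
  S4Vectors::metadata(out) <- md
  out
}
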