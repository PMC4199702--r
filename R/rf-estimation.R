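#' Tally observed genotype pairs for two markers
#'
#' Cross-tabulates the genotype calls of two markers over the individuals
#' typed at both ("dropped pairwise": an individual missing either call is
#' excluded from this pair only).
#'
#' @param genotypesA,genotypesB Equal-length character vectors of genotype
#'   codes (`"A"`, `"H"`, `"B"`, `NA`), one entry per individual.
#' @return A 3x3 integer matrix of counts with dimnames `A`, `H`, `B`
#'   (rows: first marker, columns: second marker).  The informative count
#'   is `sum()` of the table.
#' @export
pairCounts <- function(genotypesA, genotypesB) {
  if (length(genotypesA) != length(genotypesB))
    stop("genotype vectors must have equal length", call. = FALSE)
  fa <- factor(genotypesA, levels = GENO_CODES)
  fb <- factor(genotypesB, levels = GENO_CODES)
  tab <- table(fa, fb, useNA = "no")
  cnt <- matrix(as.integer(tab), 3L, 3L,
                dimnames = list(GENO_CODES, GENO_CODES))
  cnt
}

#' Pairwise log-likelihood of a recombination fraction
#'
#' Multinomial log-likelihood of the observed 3x3 genotype-pair counts
#' under the joint distribution [jointGenotypeTable()] at recombination
#' fraction `r`, for the population parameters in `model`.  Cells with a
#' positive count but zero model probability contribute `-Inf`.
#'
#' @param r Recombination fraction in [0, 0.5].
#' @param counts 3x3 count table from [pairCounts()]; fractional
#'   (expected) counts are accepted.
#' @param model A [HetModel-class].
#' @return The log-likelihood (a single number, possibly `-Inf`).
#' @export
pairLoglik <- function(r, counts, model) {
  counts <- .checkCounts(counts)
  if (sum(counts) <= 0)
    stop("no informative genotype pairs (n = 0)", call. = FALSE)
  p <- jointGenotypeTable(r, hetRetention(model), generation(model))
  used <- counts > 0
  if (any(p[used] == 0)) return(-Inf)
  sum(counts[used] * log(p[used]))
}

.checkCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)))
    stop("'counts' must be a 3x3 table", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("'counts' must be finite and non-negative", call. = FALSE)
  counts
}

# Golden-section search for the maximum of f on [lo, hi].
.goldenMax <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1)
  f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1
      x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo)
      f2 <- f(x2)
    } else {
      hi <- x2
      x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo)
      f1 <- f(x1)
    }
  }
  x <- (lo + hi) / 2
  list(maximum = x, objective = f(x))
}

#' Maximum-likelihood recombination fraction for a marker pair
#'
#' Maximizes [pairLoglik()] over \eqn{r \in [0, 0.5]} by golden-section
#' search (the bracket is trimmed by `1e-6` at each boundary so the
#' likelihood stays finite).  Requires `generation(model) >= 2`: an F1
#' carries no meiosis information.
#'
#' @inheritParams pairLoglik
#' @param tol Convergence tolerance of the search on `r`.
#' @return A list with `rf` (the estimate), `loglik` (maximized
#'   log-likelihood) and `n` (informative pair count).  Degenerate count
#'   tables (all mass in one cell) yield a boundary estimate with a
#'   warning.
#' @examples
#' m <- hetModel(7, 0.6373)
#' cnt <- 1000 * jointGenotypeTable(0.2, 0.6373, 7)  # expected counts
#' estimateRf(cnt, m)$rf                             # ~0.2
#' @export
estimateRf <- function(counts, model, tol = 1e-6) {
  counts <- .checkCounts(counts)
  if (generation(model) < 2L)
    stop("recombination fractions require generation t >= 2", call. = FALSE)
  n <- sum(counts)
  if (n <= 0)
    stop("no informative genotype pairs (n = 0)", call. = FALSE)
  if (sum(counts > 0) == 1L)
    warning("degenerate count table (single occupied cell); ",
            "returning boundary estimate")
  eps <- 1e-6
  f <- function(r) pairLoglik(r, counts, model)
  opt <- .goldenMax(f, eps, 0.5 - eps, tol)
  list(rf = opt$maximum, loglik = opt$objective, n = n)
}

#' Haldane mapping function
#'
#' Converts a recombination fraction to a Haldane map distance in
#' centimorgans, \eqn{d = -50 \ln(1 - 2r)}, and back,
#' \eqn{r = (1 - e^{-d/50})/2}.  `haldaneCM(0.5)` is `Inf`.
#'
#' @param r Recombination fraction(s) in [0, 0.5].
#' @param cM Map distance(s) in centimorgans, >= 0.
#' @return `haldaneCM()`: distances in cM; `haldaneR()`: recombination
#'   fractions.  Both are vectorized.
#' @examples
#' haldaneCM(0.1)               # 11.157...
#' haldaneR(haldaneCM(0.3))     # 0.3
#' @export
haldaneCM <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE))
    stop("'r' must be in [0, 0.5]", call. = FALSE)
  ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * r))
}

#' @rdname haldaneCM
#' @export
haldaneR <- function(cM) {
  if (any(cM < 0, na.rm = TRUE))
    stop("'cM' must be non-negative", call. = FALSE)
  (1 - exp(-cM / 50)) / 2
}

#' Recombination fractions for all adjacent marker pairs
#'
#' Estimates the recombination fraction between every pair of physically
#' adjacent markers, chromosome by chromosome (pairs never span a
#' chromosome boundary).  Pairs with no informative individuals are
#' reported with `rf = NA` and `n = 0` rather than dropped.
#'
#' @param x A [RilGenotypes-class] object.
#' @param model A [HetModel-class].
#' @param tol Search tolerance passed to [estimateRf()].
#' @return A data frame with one row per adjacent pair: `chrom`,
#'   `marker1`, `marker2`, `pos1`, `pos2`, `n`, `rf`, `loglik`.
#'   Chromosomes with fewer than two markers contribute no rows.
#' @export
adjacentRfScan <- function(x, model, tol = 1e-6) {
  stopifnot(is(x, "RilGenotypes"), is(model, "HetModel"))
  if (generation(model) < 2L)
    stop("recombination fractions require generation t >= 2", call. = FALSE)
  g <- genotypes(x)
  info <- markerInfo(x)
  out <- lapply(unique(info$chrom), function(cc) {
    idx <- which(info$chrom == cc)
    if (length(idx) < 2L) return(NULL)
    k <- idx[-length(idx)]
    res <- lapply(seq_along(k), function(j) {
      i1 <- k[j]; i2 <- k[j] + 1L
      cnt <- pairCounts(g[i1, ], g[i2, ])
      n <- sum(cnt)
      if (n == 0L)
        return(data.frame(chrom = cc, marker1 = info$marker[i1],
                          marker2 = info$marker[i2], pos1 = info$pos[i1],
                          pos2 = info$pos[i2], n = 0L, rf = NA_real_,
                          loglik = NA_real_, stringsAsFactors = FALSE))
      est <- estimateRf(cnt, model, tol = tol)
      data.frame(chrom = cc, marker1 = info$marker[i1],
                 marker2 = info$marker[i2], pos1 = info$pos[i1],
                 pos2 = info$pos[i2], n = est$n, rf = est$rf,
                 loglik = est$loglik, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), marker1 = character(),
                      marker2 = character(), pos1 = integer(),
                      pos2 = integer(), n = integer(), rf = numeric(),
                      loglik = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write adjacent-pair recombination estimates to tab-delimited text
#'
#' @param scan Data frame from [adjacentRfScan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeRfScan <- function(scan, path) {
  write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
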