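#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity show
#' @importFrom stats runif pchisq quantile
#' @importFrom utils packageVersion read.csv read.delim write.table
NULL

GENO_CODES <- c("A", "H", "B")

CLASS_NAMES <- c("parental_fixed", "recombinant_fixed", "single_het",
                 "coupling_double_het", "repulsion_double_het")

.check_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5)
    stop("'r' must be a single value in [0, 0.5]", call. = FALSE)
  invisible(r)
}

.check_h <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0 || h >= 1)
    stop("'h' must be a single value in the open interval (0, 1)",
         call. = FALSE)
  invisible(h)
}

.check_t <- function(t, min = 1L) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) ||
      t != as.integer(t) || t < min)
    stop(sprintf("'t' must be a single integer >= %d", min), call. = FALSE)
  invisible(as.integer(t))
}

#' Per-generation heterozygosity retention from observed heterozygosity
#'
#' In a population selfed from a fully heterozygous F1, a constant
#' per-generation heterozygosity retention \eqn{h} implies an observed
#' heterozygous-genotype proportion \eqn{H = h^{t-1}} at generation
#' \eqn{F_t}. `hFromH()` inverts that relation, `HFromh()` evaluates it.
#' Mendelian segregation corresponds to \eqn{h = 0.5}.
#'
#' @param H Observed proportion of heterozygous genotypes, in (0, 1).
#' @param t Selfing generation (F1 = 1); `hFromH()` requires `t >= 2`.
#' @return `hFromH()`: the per-generation retention \eqn{h};
#'   `HFromh()`: the expected heterozygous proportion \eqn{H}.
#' @examples
#' hFromH(0.067, 7)   # 0.6373: excess heterozygosity
#' HFromh(0.5, 7)     # 0.015625: Mendelian expectation at F7
#' @export
hFromH <- function(H, t) {
  if (!is.numeric(H) || length(H) != 1L || is.na(H) || H <= 0 || H >= 1)
    stop("'H' must be a single value in the open interval (0, 1)",
         call. = FALSE)
  t <- .check_t(t, min = 2L)
  exp(log(H) / (t - 1))
}

#' @param h Per-generation heterozygosity retention, in (0, 1).
#' @rdname hFromH
#' @export
HFromh <- function(h, t) {
  .check_h(h)
  t <- .check_t(t, min = 1L)
  h^(t - 1)
}

#' Heterozygote viability implied by a heterozygosity-retention target
#'
#' For a double-heterozygous two-locus genotype under selfing, the model
#' assigns each heterozygous locus of an offspring a relative viability
#' `u` (homozygous loci have viability 1).  `u` is chosen so that the
#' heterozygosity retained in one generation of segregation from a double
#' heterozygote equals `h`:  writing \eqn{a = (1-r)^2 + r^2} and
#' \eqn{b = 4r(1-r)}, `u` is the unique positive root of
#' \deqn{2a(h-1)u^2 + b(2h-1)u + 2ah = 0.}
#' The normalizer of the double-heterozygote segregation ratios is
#' \deqn{d = 2(1-r)^2 + 8ur(1-r) + 2r^2 + 2u^2[(1-r)^2 + r^2].}
#'
#' @param h Per-generation heterozygosity retention, in (0, 1).
#' @param r Recombination fraction between the two loci, in [0, 0.5].
#' @return A list with elements `u` (heterozygote relative viability) and
#'   `d` (normalizing denominator).  `u = 1` exactly when `h = 0.5`.
#' @examples
#' solveViability(0.5, 0.25)$u       # 1: Mendelian, no advantage
#' solveViability(0.6373, 0)$u       # sqrt(h/(1-h))
#' @export
solveViability <- function(h, r) {
  .check_h(h)
  .check_r(r)
  a <- (1 - r)^2 + r^2
  b <- 4 * r * (1 - r)
  A <- 2 * a * (h - 1)       # < 0 for h in (0,1)
  B <- b * (2 * h - 1)
  C <- 2 * a * h             # > 0
  disc <- B^2 - 4 * A * C    # > B^2 since A*C < 0
  if (!is.finite(disc) || disc < 0)
    stop("viability root finding failed: negative discriminant",
         call. = FALSE)
  u <- (B + sqrt(disc)) / (-2 * A)
  if (!is.finite(u) || u <= 0)
    stop("viability root finding failed: no positive root", call. = FALSE)
  d <- 2 * (1 - r)^2 + 8 * u * r * (1 - r) + 2 * r^2 + 2 * u^2 * a
  list(u = u, d = d)
}

#' Transition matrix of the five-class selfing Markov chain
#'
#' Two linked loci in a selfed line occupy one of five symmetry-collapsed
#' genotype classes: (1) parental fixed, (2) recombinant fixed, (3) single
#' heterozygote, (4) coupling double heterozygote (AB/ab), (5) repulsion
#' double heterozygote (Ab/aB).  Column `j` gives the class distribution
#' of the selfed offspring of a class-`j` parent.  Classes 1 and 2 are
#' absorbing; class 3 retains heterozygosity at rate `h`; classes 4 and 5
#' segregate with heterozygote viability `u` from [solveViability()].
#'
#' @inheritParams solveViability
#' @return A 5x5 column-stochastic matrix.
#' @seealso [classProbabilities()], [solveViability()]
#' @export
transitionMatrix <- function(r, h) {
  .check_r(r)
  .check_h(h)
  vb <- solveViability(h, r)
  u <- vb$u
  d <- vb$d
  cc <- (1 - r)^2   # coupling (parental-phase) gamete pair weight
  rr <- r^2
  col4 <- c(2 * cc, 2 * rr, 8 * u * r * (1 - r), 2 * u^2 * cc, 2 * u^2 * rr) / d
  col5 <- col4[c(2L, 1L, 3L, 5L, 4L)]
  T <- cbind(
    c(1, 0, 0, 0, 0),
    c(0, 1, 0, 0, 0),
    c((1 - h) / 2, (1 - h) / 2, h, 0, 0),
    col4,
    col5
  )
  dimnames(T) <- list(CLASS_NAMES, CLASS_NAMES)
  T
}

#' Genotype-class probabilities at generation t
#'
#' Propagates the class distribution from the F1 initial condition
#' (all mass on the coupling double heterozygote) through `t - 1` rounds
#' of selfing with the transition matrix of [transitionMatrix()].
#'
#' @inheritParams solveViability
#' @param t Selfing generation (integer, F1 = 1).
#' @return A named probability 5-vector over the genotype classes.
#' @examples
#' classProbabilities(0.25, 0.5, 2)  # classical two-locus F2 frequencies
#' @export
classProbabilities <- function(r, h, t) {
  t <- .check_t(t, min = 1L)
  p <- c(0, 0, 0, 1, 0)
  if (t > 1L) {
    T <- transitionMatrix(r, h)
    for (i in seq_len(t - 1L)) p <- as.vector(T %*% p)
  }
  names(p) <- CLASS_NAMES
  p
}

#' Joint distribution of observable two-locus genotypes
#'
#' Unfolds the five-class distribution of [classProbabilities()] into the
#' 3x3 table of observable genotype pairs, with genotypes coded
#' `A` (homozygous parent 1), `H` (heterozygous), `B` (homozygous
#' parent 2) at each locus.  Members of a class are equiprobable (the
#' selfing symmetry that defines the classes), and the two
#' double-heterozygote phase classes are merged because they are
#' observationally indistinguishable.
#'
#' @inheritParams classProbabilities
#' @return A 3x3 matrix of probabilities; rows index the first locus,
#'   columns the second, both named `A`, `H`, `B`.  Each marginal puts
#'   probability `h^(t-1)` on `H`.
#' @export
jointGenotypeTable <- function(r, h, t) {
  p <- classProbabilities(r, h, t)
  tab <- matrix(0, 3L, 3L, dimnames = list(GENO_CODES, GENO_CODES))
  tab["A", "A"] <- p[1L] / 2
  tab["B", "B"] <- p[1L] / 2
  tab["A", "B"] <- p[2L] / 2
  tab["B", "A"] <- p[2L] / 2
  tab["H", "A"] <- p[3L] / 4
  tab["H", "B"] <- p[3L] / 4
  tab["A", "H"] <- p[3L] / 4
  tab["B", "H"] <- p[3L] / 4
  tab["H", "H"] <- p[4L] + p[5L]
  tab
}
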