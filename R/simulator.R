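# Evaluate expr with a temporary RNG seed, restoring the caller's state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
              add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Simulate a RIL genotype matrix under the heterozygosity model
#'
#' Generates one linkage group of equally spaced markers for a selfed RIL
#' population at generation `t` with per-generation heterozygosity
#' retention `h`.  Genotypes are drawn as a first-order chain along the
#' chromosome: the first marker from the model's marginal
#' `((1-H)/2, H, (1-H)/2)` with `H = h^(t-1)`, and each subsequent marker
#' from the conditional distribution implied by [jointGenotypeTable()] at
#' the adjacent-pair recombination fraction.  The simulated data therefore
#' obey exactly the pairwise distributions the recombination-fraction
#' estimator assumes; dependence beyond adjacent pairs is first-order
#' Markov.  Genotyping noise, if requested, is applied by [injectNoise()].
#'
#' @param nIndividuals,nMarkers Population and marker-panel size (>= 1).
#' @param mapLengthCM Length of the linkage group in centimorgans;
#'   adjacent markers are `mapLengthCM / (nMarkers - 1)` cM apart.
#' @param t Selfing generation (integer >= 1).
#' @param h Per-generation heterozygosity retention in (0, 1).
#' @param errorRate,missingRate Genotyping noise rates in [0, 1].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param chrom Chromosome name for the simulated linkage group.
#' @param bpPerMarker Physical spacing between adjacent markers (bp).
#' @return A [RilGenotypes-class] object (markers x individuals).
#' @examples
#' sim <- simulatePopulation(200, 50, 100, t = 7, h = 0.6373, seed = 1)
#' estimateH(sim)   # about 0.067
#' @export
simulatePopulation <- function(nIndividuals, nMarkers, mapLengthCM, t, h,
                               errorRate = 0, missingRate = 0, seed = NULL,
                               chrom = "1", bpPerMarker = 10000L) {
  if (nIndividuals < 1L || nMarkers < 1L || mapLengthCM < 0)
    stop("invalid simulation configuration", call. = FALSE)
  t <- .check_t(t, min = 1L)
  .check_h(h)
  .withSeed(seed, {
    Hm <- h^(t - 1L)
    marg <- c((1 - Hm) / 2, Hm, (1 - Hm) / 2)
    gi <- matrix(0L, nMarkers, nIndividuals)
    gi[1L, ] <- sample.int(3L, nIndividuals, replace = TRUE, prob = marg)
    if (nMarkers > 1L) {
      rAdj <- haldaneR(mapLengthCM / (nMarkers - 1L))
      joint <- jointGenotypeTable(rAdj, h, t)
      cond <- joint / rowSums(joint)
      cum1 <- cumsum(cond[1L, ])
      cum2 <- cumsum(cond[2L, ])
      cum3 <- cumsum(cond[3L, ])
      c1 <- rbind(cum1, cum2, cum3)[, 1L]
      c2 <- rbind(cum1, cum2, cum3)[, 2L]
      for (k in 2L:nMarkers) {
        prev <- gi[k - 1L, ]
        uu <- runif(nIndividuals)
        gi[k, ] <- 1L + (uu > c1[prev]) + (uu > c2[prev])
      }
    }
    g <- matrix(GENO_CODES[gi], nMarkers, nIndividuals,
                dimnames = list(sprintf("M%04d", seq_len(nMarkers)),
                                sprintf("I%04d", seq_len(nIndividuals))))
    x <- rilGenotypes(g, chrom = chrom,
                      pos = as.integer((seq_len(nMarkers) - 1L)) *
                        as.integer(bpPerMarker) + 1L)
    if (errorRate > 0 || missingRate > 0)
      x <- injectNoise(x, errorRate = errorRate, missingRate = missingRate)
    x
  })
}

#' Add genotyping errors and missing calls
#'
#' Each genotype call is independently set to missing with probability
#' `missingRate`; each surviving call is then replaced, with probability
#' `errorRate`, by one of the other two genotype codes chosen uniformly
#' (symmetric misclassification).
#'
#' @param x A [RilGenotypes-class] object.
#' @param errorRate,missingRate Rates in [0, 1].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return The perturbed object.
#' @export
injectNoise <- function(x, errorRate, missingRate, seed = NULL) {
  stopifnot(is(x, "RilGenotypes"))
  if (errorRate < 0 || errorRate > 1 || missingRate < 0 || missingRate > 1)
    stop("noise rates must be in [0, 1]", call. = FALSE)
  .withSeed(seed, {
    g <- genotypes(x)
    if (missingRate > 0)
      g[runif(length(g)) < missingRate] <- NA_character_
    if (errorRate > 0) {
      hit <- which(!is.na(g) & runif(length(g)) < errorRate)
      if (length(hit)) {
        cur <- match(g[hit], GENO_CODES)
        shift <- sample.int(2L, length(hit), replace = TRUE)
        g[hit] <- GENO_CODES[((cur - 1L + shift) %% 3L) + 1L]
      }
    }
    out <- x
    SummarizedExperiment::assay(out, "geno") <- g
    out
  })
}

# One round of gamete formation for all lines: no-interference crossovers
# (independent exchange between adjacent loci with probability r).
.drawGametes <- function(hap1, hap2, r) {
  n <- nrow(hap1)
  L <- ncol(hap1)
  cur <- sample.int(2L, n, replace = TRUE)   # 1 -> hap1, 2 -> hap2
  gam <- matrix(0L, n, L)
  gam[, 1L] <- ifelse(cur == 1L, hap1[, 1L], hap2[, 1L])
  if (L > 1L) {
    for (k in 2L:L) {
      sw <- runif(n) < r[k - 1L]
      cur <- ifelse(sw, 3L - cur, cur)
      gam[, k] <- ifelse(cur == 1L, hap1[, k], hap2[, k])
    }
  }
  gam
}

#' Forward-in-time selfing simulator with zygotic viability selection
#'
#' An explicit generation-by-generation simulator used as an independent
#' cross-check of the class Markov chain.  Lines start as fully
#' heterozygous F1 individuals; each generation one selfed offspring per
#' line is formed from two gametes drawn with no-interference crossovers
#' and accepted by rejection sampling on its zygotic viability.
#'
#' With `mode = "viability"`, selection follows the model's two regimes:
#' offspring of a parent heterozygous at a single locus carry relative
#' viability `h/(1-h)` per heterozygous locus (which makes the retained
#' heterozygosity exactly `h`), and offspring of a double-heterozygous
#' parent carry viability `u` per heterozygous locus, with `u` from
#' [solveViability()] at the locus pair's recombination fraction.  This
#' regime structure is what the class transition matrix encodes, so the
#' simulator reproduces it without sharing any of its code; it is limited
#' to one or two loci.  With `mode = "mendelian"` all offspring are
#' accepted (`u = 1`) and any number of loci is allowed.
#'
#' @param nLines Number of independent lines.
#' @param t Selfing generation to simulate to (F1 = 1).
#' @param h Per-generation heterozygosity retention in (0, 1).
#' @param r Recombination fraction(s) between adjacent loci; the number of
#'   loci is `length(r) + 1` (use `r = numeric(0)` for a single locus).
#' @param mode `"viability"` (model selection) or `"mendelian"`.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param maxRounds Cap on rejection-sampling rounds per generation; an
#'   error is raised if any line is still unresolved at the cap.
#' @return A list with integer haplotype matrices `hap1`, `hap2`
#'   (lines x loci; 0 = parent-1 allele) and `geno`, a loci x lines
#'   character matrix of genotype codes.
#' @seealso [classifyTwoLocus()] to collapse two-locus output into the
#'   five genotype classes.
#' @export
simulateForward <- function(nLines, t, h, r = numeric(0),
                            mode = c("viability", "mendelian"),
                            seed = NULL, maxRounds = 10000L) {
  mode <- match.arg(mode)
  t <- .check_t(t, min = 1L)
  .check_h(h)
  L <- length(r) + 1L
  if (any(r < 0 | r > 0.5))
    stop("'r' values must be in [0, 0.5]", call. = FALSE)
  if (mode == "viability" && L > 2L)
    stop("viability mode supports at most two loci", call. = FALSE)
  .withSeed(seed, {
    hap1 <- matrix(0L, nLines, L)
    hap2 <- matrix(1L, nLines, L)
    wHet <- h / (1 - h)
    uPair <- if (L == 2L) solveViability(h, r[1L])$u else NA_real_
    for (gen in seq_len(t - 1L)) {
      pendingIdx <- seq_len(nLines)
      p1 <- hap1
      p2 <- hap2
      round <- 0L
      while (length(pendingIdx)) {
        round <- round + 1L
        if (round > maxRounds)
          stop("rejection sampling did not resolve within 'maxRounds'",
               call. = FALSE)
        ph1 <- p1[pendingIdx, , drop = FALSE]
        ph2 <- p2[pendingIdx, , drop = FALSE]
        g1 <- .drawGametes(ph1, ph2, r)
        g2 <- .drawGametes(ph1, ph2, r)
        if (mode == "mendelian") {
          acc <- rep(TRUE, length(pendingIdx))
        } else {
          nPh <- rowSums(ph1 != ph2)
          nOh <- rowSums(g1 != g2)
          w <- rep(1, length(pendingIdx))
          one <- nPh == 1L
          two <- nPh == 2L
          w[one] <- wHet^nOh[one]
          w[two] <- uPair^nOh[two]
          wmax <- rep(1, length(pendingIdx))
          wmax[one] <- max(1, wHet)
          wmax[two] <- max(1, uPair)^2
          acc <- runif(length(pendingIdx)) < w / wmax
        }
        done <- pendingIdx[acc]
        hap1[done, ] <- g1[acc, , drop = FALSE]
        hap2[done, ] <- g2[acc, , drop = FALSE]
        pendingIdx <- pendingIdx[!acc]
      }
    }
    het <- hap1 != hap2
    code <- matrix("H", nLines, L)
    code[!het & hap1 == 0L] <- "A"
    code[!het & hap1 == 1L] <- "B"
    list(hap1 = hap1, hap2 = hap2, geno = t(code))
  })
}

#' Collapse two-locus forward-simulation output into genotype classes
#'
#' Assigns each line of a two-locus [simulateForward()] result to one of
#' the five symmetry-collapsed genotype classes (parental fixed,
#' recombinant fixed, single heterozygote, coupling double heterozygote,
#' repulsion double heterozygote).  Phase is resolved from the haplotypes,
#' so the two double-heterozygote classes are distinguished.
#'
#' @param sim A list from [simulateForward()] with exactly two loci.
#' @return An integer vector of class indices (1-5), one per line.
#' @export
classifyTwoLocus <- function(sim) {
  hap1 <- sim$hap1
  hap2 <- sim$hap2
  if (ncol(hap1) != 2L)
    stop("classifyTwoLocus() requires exactly two loci", call. = FALSE)
  hetA <- hap1[, 1L] != hap2[, 1L]
  hetB <- hap1[, 2L] != hap2[, 2L]
  cls <- integer(nrow(hap1))
  fixed <- !hetA & !hetB
  cls[fixed & hap1[, 1L] == hap1[, 2L]] <- 1L   # parental: AB/AB or ab/ab
  cls[fixed & hap1[, 1L] != hap1[, 2L]] <- 2L   # recombinant: Ab/Ab, aB/aB
  cls[xor(hetA, hetB)] <- 3L
  doub <- hetA & hetB
  coupling <- hap1[, 1L] == hap1[, 2L] & hap2[, 1L] == hap2[, 2L]
  cls[doub & coupling] <- 4L
  cls[doub & !coupling] <- 5L
  cls
}
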