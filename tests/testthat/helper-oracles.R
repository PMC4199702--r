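# Independent oracles, coded from the classical theory rather than from the
# package's transition-matrix implementation.

# Classical Mendelian two-locus selfing recursion: class transitions for a
# selfed line with no viability term, written directly from the textbook
# gamete frequencies ((1-r)/2 coupling, r/2 recombinant per gamete).
mendelianClassProbs <- function(r, t) {
  Tm <- cbind(
    c(1, 0, 0, 0, 0),
    c(0, 1, 0, 0, 0),
    c(1 / 4, 1 / 4, 1 / 2, 0, 0),
    c((1 - r)^2 / 2, r^2 / 2, 2 * r * (1 - r), (1 - r)^2 / 2, r^2 / 2),
    c(r^2 / 2, (1 - r)^2 / 2, 2 * r * (1 - r), r^2 / 2, (1 - r)^2 / 2)
  )
  p <- c(0, 0, 0, 1, 0)
  if (t > 1) for (i in seq_len(t - 1)) p <- as.vector(Tm %*% p)
  p
}

# Observable 3x3 genotype-pair table from the classical recursion.
mendelianJointTable <- function(r, t) {
  p <- mendelianClassProbs(r, t)
  tab <- matrix(0, 3, 3, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
  tab["A", "A"] <- tab["B", "B"] <- p[1] / 2
  tab["A", "B"] <- tab["B", "A"] <- p[2] / 2
  tab["A", "H"] <- tab["B", "H"] <- tab["H", "A"] <- tab["H", "B"] <- p[3] / 4
  tab["H", "H"] <- p[4] + p[5]
  tab
}

# Independent Mendelian recombination-fraction fit: Brent optimizer
# (stats::optimize) over the classical likelihood, sharing neither the
# search code nor the genotype-table code with the package.
mendelianRfFit <- function(counts, t) {
  nll <- function(r) {
    tab <- mendelianJointTable(r, t)
    used <- counts > 0
    if (any(tab[used] == 0)) return(Inf)
    -sum(counts[used] * log(tab[used]))
  }
  stats::optimize(nll, c(1e-6, 0.5 - 1e-6), tol = 1e-9)$minimum
}

# Reference tight-double-recombination masker: per-call scan over a single
# genotype vector, O(n^2), decisions on the input snapshot.
refTightDoubleMask <- function(geno, pos, window) {
  n <- length(geno)
  mask <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(geno[i])) next
    # extend over the run of identical non-missing calls containing i
    # (missing calls are transparent)
    obs <- which(!is.na(geno))
    k <- match(i, obs)
    lo <- k
    while (lo > 1 && geno[obs[lo - 1]] == geno[i]) lo <- lo - 1
    hi <- k
    while (hi < length(obs) && geno[obs[hi + 1]] == geno[i]) hi <- hi + 1
    if (lo == 1 || hi == length(obs)) next        # chromosome end: no flank
    left <- obs[lo - 1]
    right <- obs[hi + 1]
    if (geno[left] != geno[right]) next           # flanks must agree
    if (pos[right] - pos[left] <= window) mask[i] <- TRUE
  }
  mask
}

# Small deterministic genotype object for filter tests.
makeGeno <- function(g, chrom = "1", pos = NULL) {
  g <- as.matrix(g)
  if (is.null(pos)) pos <- seq_len(nrow(g)) * 1000L
  if (is.null(rownames(g))) rownames(g) <- sprintf("m%02d", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- sprintf("i%02d", seq_len(ncol(g)))
  rilGenotypes(g, chrom = chrom, pos = pos)
}
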