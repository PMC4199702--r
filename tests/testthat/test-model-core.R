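test_that("h/H conversions invert each other and match known values", {
  expect_equal(round(hFromH(0.067, 7), 4), 0.6373)
  expect_equal(hFromH(0.25, 3), 0.5)
  expect_equal(hFromH(0.015625, 7), 0.5)
  expect_equal(HFromh(0.5, 7), 0.015625)
  expect_equal(HFromh(0.789, 1), 1)        # F1 fully heterozygous
  expect_equal(round(HFromh(0.6373, 7), 3), 0.067)
  for (h in c(0.3, 0.5, 0.6373, 0.9))
    expect_equal(hFromH(HFromh(h, 6), 6), h, tolerance = 1e-12)
  expect_error(hFromH(0, 7), "open interval")
  expect_error(hFromH(1, 7), "open interval")
  expect_error(hFromH(0.1, 1), "integer")
})

test_that("viability root satisfies the retention constraint", {
  for (r in c(0, 0.1, 0.25, 0.4, 0.5))
    expect_equal(solveViability(0.5, r)$u, 1, tolerance = 1e-12)
  # closed form at complete linkage
  expect_equal(solveViability(0.6373, 0)$u, sqrt(0.6373 / (1 - 0.6373)),
               tolerance = 1e-12)
  # plugging (u, d) back into the retention identity reproduces h
  for (h in c(0.2, 0.5, 0.6373, 0.85)) {
    for (r in c(0, 0.05, 0.25, 0.5)) {
      v <- solveViability(h, r)
      T <- transitionMatrix(r, h)
      expect_lt(abs(T[3, 4] / 2 + T[4, 4] + T[5, 4] - h), 1e-10)
      expect_gt(v$d, 0)
    }
  }
  # closed-form root agrees with a brute-force scan of the constraint
  h <- 0.6373; r <- 0.25
  a <- (1 - r)^2 + r^2
  resid <- function(u) {
    d <- 2 * (1 - r)^2 + 8 * u * r * (1 - r) + 2 * r^2 + 2 * u^2 * a
    (4 * u * r * (1 - r) + 2 * u^2 * a) / d - h
  }
  grid <- seq(1e-4, 10, by = 1e-4)
  uScan <- grid[which.min(abs(resid(grid)))]
  expect_equal(solveViability(h, r)$u, uScan, tolerance = 1e-3)
  expect_lt(abs(resid(solveViability(h, r)$u)), 1e-10)
  # continuity toward the Mendelian point
  expect_equal(solveViability(0.5 + 1e-9, 0.2)$u, 1, tolerance = 1e-6)
  expect_error(solveViability(1.2, 0.1), "open interval")
})

test_that("transition matrix is column-stochastic with absorbing fixed classes", {
  for (h in seq(0.1, 0.9, by = 0.1)) {
    for (r in c(0, 0.01, 0.1, 0.25, 0.4, 0.5)) {
      T <- transitionMatrix(r, h)
      expect_true(all(T >= 0))
      expect_lt(max(abs(colSums(T) - 1)), 1e-12)
      expect_equal(T[, 1], c(1, 0, 0, 0, 0), ignore_attr = TRUE)
      expect_equal(T[, 2], c(0, 1, 0, 0, 0), ignore_attr = TRUE)
      expect_equal(T[, 3], c((1 - h) / 2, (1 - h) / 2, h, 0, 0),
                   ignore_attr = TRUE)
    }
  }
  # complete linkage, Mendelian: double het fixes or persists, half-half
  T0 <- transitionMatrix(0, 0.5)
  expect_equal(T0[, 4], c(0.5, 0, 0, 0.5, 0), ignore_attr = TRUE)
  # unlinked loci: coupling and repulsion have identical gametic output
  T5 <- transitionMatrix(0.5, 0.5)
  expect_equal(T5[, 4], T5[, 5], ignore_attr = TRUE)
})

test_that("class probabilities: F2 closed form, normalization, no-recombination case", {
  for (r in c(0.05, 0.25, 0.5)) {
    p <- classProbabilities(r, 0.5, 2)
    expect_equal(unname(p),
                 c((1 - r)^2 / 2, r^2 / 2, 2 * r * (1 - r),
                   (1 - r)^2 / 2, r^2 / 2),
                 tolerance = 1e-12)
  }
  expect_equal(unname(classProbabilities(0.3, 0.6373, 1)), c(0, 0, 0, 1, 0))
  for (t in c(2, 5, 9)) {
    p <- classProbabilities(0, 0.6373, t)
    expect_equal(p[["recombinant_fixed"]], 0)
    expect_equal(p[["repulsion_double_het"]], 0)
  }
  for (h in c(0.3, 0.6373)) {
    for (r in c(0, 0.2, 0.5)) {
      for (t in c(2, 7, 30)) {
        p <- classProbabilities(r, h, t)
        expect_true(all(p >= 0))
        expect_lt(abs(sum(p) - 1), 1e-12)
      }
    }
  }
})

test_that("Mendelian case reduces to the classical selfing recursion", {
  for (r in c(0, 0.05, 0.2, 0.35, 0.5)) {
    for (t in 1:20) {
      expect_equal(unname(classProbabilities(r, 0.5, t)),
                   mendelianClassProbs(r, t), tolerance = 1e-12)
    }
  }
})

test_that("fixed lines approach the classical recombinant fraction 2r/(1+2r)", {
  for (r in c(0.1, 0.25, 0.4)) {
    p <- classProbabilities(r, 0.5, 200)
    expect_equal(p[[2]] / (p[[1]] + p[[2]]), 2 * r / (1 + 2 * r),
                 tolerance = 1e-9)
  }
})

test_that("joint genotype table sums to 1 with heterozygosity-conserving marginals", {
  for (h in c(0.25, 0.5, 0.6373)) {
    for (r in c(0, 0.1, 0.3, 0.5)) {
      for (t in c(2, 7, 15)) {
        tab <- jointGenotypeTable(r, h, t)
        expect_lt(abs(sum(tab) - 1), 1e-12)
        expect_true(all(tab >= 0))
        expect_lt(abs(sum(tab["H", ]) - h^(t - 1)), 1e-10)
        expect_lt(abs(sum(tab[, "H"]) - h^(t - 1)), 1e-10)
        # allele-swap symmetry
        expect_equal(tab["A", "A"], tab["B", "B"])
        expect_equal(tab["A", "B"], tab["B", "A"])
        expect_equal(tab["H", "A"], tab["H", "B"])
        expect_equal(tab["A", "H"], tab["B", "H"])
      }
    }
  }
  # unlinked loci at F2 factorize into the 1:2:1 outer product
  expect_equal(unname(jointGenotypeTable(0.5, 0.5, 2)),
               outer(c(1, 2, 1) / 4, c(1, 2, 1) / 4), tolerance = 1e-12)
})

test_that("hetModel validates and reports its parameters", {
  m <- hetModel(7, 0.6373)
  expect_s4_class(m, "HetModel")
  expect_identical(generation(m), 7L)
  expect_equal(hetRetention(m), 0.6373)
  m2 <- hetModelFromH(0.067, 7)
  expect_equal(round(hetRetention(m2), 4), 0.6373)
  expect_error(hetModel(0, 0.5))
  expect_error(hetModel(7, 1.2))
  expect_output(show(m), "F7")
})
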