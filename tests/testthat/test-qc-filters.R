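test_that("estimateH counts heterozygous calls among non-missing genotypes", {
  x <- makeGeno(rbind(c("H", "H"), c("H", "H")))
  expect_equal(estimateH(x), 1)
  g <- matrix("A", 10, 100)
  g[1, 1:74] <- "H"
  g[2, 1:26] <- NA
  x <- makeGeno(g)
  expect_equal(estimateH(x), 74 / (1000 - 26))
  byChr <- estimateH(makeGeno(rbind(c("H", "A"), c("A", "A")),
                              chrom = c("1", "2")), byChromosome = TRUE)
  expect_equal(unname(byChr), c(0.5, 0))
  expect_error(estimateH(makeGeno(matrix(NA_character_, 2, 2))),
               "non-missing")
})

test_that("distortion test matches the chi-square null and drives retention", {
  expect_equal(distortionTest(463, 74, 463, Hnull = 0.074), 1)
  # (500, 0, 500) against 1:2:1 — direct chi-square arithmetic
  expd <- 1000 * c(0.25, 0.5, 0.25)
  stat <- sum((c(500, 0, 500) - expd)^2 / expd)
  expect_equal(distortionTest(500, 0, 500, 0.5, log.p = TRUE),
               pchisq(stat, 2, lower.tail = FALSE, log.p = TRUE))
  expect_lt(distortionTest(500, 0, 500, 0.5), 1e-15)
  # the null choice flips the exclusion decision for low-het data
  expect_gt(distortionTest(199, 2, 199, Hnull = 0.005), 1e-15)
  expect_lt(distortionTest(199, 2, 199, Hnull = 0.5), 1e-15)
  # Mendelian null equals the textbook 1:2:1 test
  o <- c(120, 230, 150)
  stat121 <- sum((o - 500 * c(0.25, 0.5, 0.25))^2 / (500 * c(0.25, 0.5, 0.25)))
  expect_equal(distortionTest(o[1], o[2], o[3], 0.5),
               pchisq(stat121, df = 2, lower.tail = FALSE))
  expect_error(distortionTest(0, 0, 0, 0.5), "zero")
})

test_that("distortion filter removes markers below alpha, with per-chromosome overrides", {
  set.seed(5)
  # marker rows: one wildly distorted, others near a 46:8:46-ish null
  gOk <- t(replicate(20, sample(c("A", "H", "B"), 100, replace = TRUE,
                                prob = c(0.46, 0.08, 0.46))))
  gBad <- matrix(rep(c("A"), 100), 1)
  g <- rbind(gOk[1:10, ], gBad, gOk[11:20, ])
  rownames(g) <- sprintf("m%02d", 1:21)
  x <- makeGeno(g, chrom = rep(c("1", "2"), c(11, 10)))
  out <- filterMarkersByDistortion(x, Hnull = 0.08, alpha = 1e-15)
  expect_equal(nrow(out), 20L)
  rep1 <- qcReports(out)[[1]]
  expect_equal(rep1@removedMarkers$marker, "m11")
  # alpha = 0 removes nothing
  expect_equal(nrow(filterMarkersByDistortion(x, 0.08, alpha = 0)), 21L)
  # relaxing the threshold for the distorted marker's chromosome keeps it
  out2 <- filterMarkersByDistortion(x, Hnull = 0.08, alpha = 1e-15,
                                    overrides = c("1" = 1e-300))
  expect_equal(nrow(out2), 21L)
  # type-I control on clean simulated data at matching null
  sim <- simulatePopulation(300, 400, 100, t = 7, h = 0.6373, seed = 9)
  Hnull <- 0.6373^6
  kept <- filterMarkersByDistortion(sim, Hnull = Hnull, alpha = 0.05)
  removedFrac <- 1 - nrow(kept) / nrow(sim)
  expect_lt(removedFrac, 0.12)   # ~alpha, allowing Markov-chain correlation
})

test_that("missingness filter applies >= thresholds, markers before individuals", {
  g <- matrix("A", 10, 10, dimnames = list(sprintf("m%02d", 1:10),
                                           sprintf("i%02d", 1:10)))
  x <- makeGeno(g)
  out <- filterMissingness(x)
  expect_equal(dim(out), c(10L, 10L))
  g2 <- g; g2[1, 1:6] <- NA                  # marker at exactly 60%
  out <- filterMissingness(makeGeno(g2))
  expect_equal(rownames(out), sprintf("m%02d", 2:10))
  g3 <- g; g3[1, 1:5] <- NA; g3[2, 1:6] <- NA   # 50% kept, 60% removed
  out <- filterMissingness(makeGeno(g3))
  expect_false("m02" %in% rownames(out))
  expect_true("m01" %in% rownames(out))
  # individual judged on markers remaining after the marker filter
  g4 <- g
  g4[1:6, 1] <- NA                      # individual i01 60% missing
  out <- filterMissingness(makeGeno(g4))
  expect_false("i01" %in% colnames(out))
  expect_error(filterMissingness(x, maxMarkerMissing = 1.5), "\\[0, 1\\]")
})

test_that("duplicate-individual removal keeps one representative per group", {
  set.seed(7)
  base <- sample(c("A", "H", "B"), 100, replace = TRUE, prob = c(.46, .08, .46))
  other <- sample(c("A", "H", "B"), 100, replace = TRUE, prob = c(.46, .08, .46))
  dup <- base
  dup[1:3] <- NA                        # duplicate with more missingness
  g <- cbind(i1 = base, i2 = dup, i3 = other)
  x <- makeGeno(matrix(g, nrow = 100, dimnames = list(NULL, colnames(g))))
  out <- dropDuplicateIndividuals(x, minShare = 0.9)
  expect_equal(colnames(out), c("i1", "i3"))   # lower missingness kept
  # 89% sharing: both retained
  part <- base
  part[1:11] <- c(A = "B", H = "A", B = "H")[base[1:11]]  # force mismatches
  shared <- mean(part == base)
  expect_lt(shared, 0.9)
  x2 <- makeGeno(matrix(cbind(base, part), nrow = 100,
                        dimnames = list(NULL, c("i1", "i2"))))
  expect_equal(ncol(dropDuplicateIndividuals(x2, minShare = 0.9)), 2L)
})

test_that("duplicate chains resolve by connected component with one survivor", {
  # A~B and B~C above threshold, A~C below: one component, keep least missing
  a <- rep(c("A", "B"), 50)
  b <- a; b[1:8] <- "H"                  # A~B share 92%
  cc <- b; cc[93:100] <- "H"             # B~C share 92%, A~C share 84%
  g <- cbind(A = a, B = b, C = cc)
  x <- makeGeno(matrix(g, nrow = 100, dimnames = list(NULL, colnames(g))))
  out <- dropDuplicateIndividuals(x, minShare = 0.9)
  expect_equal(ncol(out), 1L)            # whole component collapses
  expect_equal(colnames(out), "A")       # tie on missingness -> input order
})

test_that("tight double recombinant masking matches a brute-force reference", {
  # canonical case: A A B A A at 1 kb spacing, 2 kb window
  g <- matrix(c("A", "A", "B", "A", "A"), 5, 1,
              dimnames = list(sprintf("m%d", 1:5), "i1"))
  x <- rilGenotypes(g, chrom = "1", pos = c(1L, 1001L, 2001L, 3001L, 4001L))
  out <- maskTightDoubleRecombinants(x, window = 2000, units = "bp")
  expect_true(is.na(genotypes(out)["m3", 1]))
  expect_equal(sum(is.na(genotypes(out))), 1L)
  # interior span beyond window: unchanged
  g2 <- matrix(c("A", "A", "B", "B", "B", "A", "A"), 7, 1,
               dimnames = list(sprintf("m%d", 1:7), "i1"))
  x2 <- rilGenotypes(g2, chrom = "1", pos = as.integer(seq(1, 6001, by = 1000)))
  out2 <- maskTightDoubleRecombinants(x2, window = 2000, units = "bp")
  expect_identical(genotypes(out2), genotypes(x2))
  # exhaustive: all length-5 patterns against the reference implementation
  codes <- c("A", "H", "B", NA)
  pats <- as.matrix(expand.grid(codes, codes, codes, codes, codes,
                                stringsAsFactors = FALSE))
  gAll <- t(pats)
  dimnames(gAll) <- list(sprintf("m%d", 1:5), sprintf("p%04d", seq_len(nrow(pats))))
  pos <- c(1L, 1001L, 2001L, 3001L, 4001L)
  xAll <- rilGenotypes(gAll, chrom = "1", pos = pos)
  outAll <- genotypes(maskTightDoubleRecombinants(xAll, 2000, units = "bp"))
  for (j in seq_len(ncol(gAll))) {
    ref <- refTightDoubleMask(gAll[, j], pos, 2000)
    got <- unname(is.na(outAll[, j]) & !is.na(gAll[, j]))
    expect_identical(got, ref)
    # masking only ever sets calls to missing
    keptSame <- !is.na(outAll[, j])
    expect_identical(unname(outAll[keptSame, j]),
                     unname(gAll[keptSame, j]))
  }
  # cM mode requires a map
  expect_error(maskTightDoubleRecombinants(x, 2, units = "cM"), "map")
  map <- data.frame(marker = rownames(g), cM = c(0, 0.5, 1.0, 1.5, 2.0))
  outCm <- maskTightDoubleRecombinants(x, 2, units = "cM", map = map)
  expect_true(is.na(genotypes(outCm)["m3", 1]))
})

test_that("QC filters are idempotent", {
  sim <- simulatePopulation(60, 40, 80, t = 7, h = 0.6373,
                            errorRate = 0.02, missingRate = 0.1, seed = 13)
  once <- filterMissingness(sim)
  twice <- filterMissingness(once)
  expect_identical(genotypes(twice), genotypes(once))
  onceD <- dropDuplicateIndividuals(sim)
  twiceD <- dropDuplicateIndividuals(onceD)
  expect_identical(genotypes(twiceD), genotypes(onceD))
  onceM <- maskTightDoubleRecombinants(sim, 20000, units = "bp")
  twiceM <- maskTightDoubleRecombinants(onceM, 20000, units = "bp")
  expect_identical(genotypes(twiceM), genotypes(onceM))
  # masking only converts calls to missing, never to another call
  gIn <- genotypes(sim)
  gOut <- genotypes(onceM)
  same <- !is.na(gOut)
  expect_identical(gOut[same], gIn[same])
})

test_that("outlier flagging catches gross heterozygosity excess only", {
  set.seed(17)
  g <- replicate(40, sample(c("A", "H", "B"), 200, replace = TRUE,
                            prob = c(0.467, 0.067, 0.467)))
  weird <- sample(c("A", "H", "B"), 200, replace = TRUE,
                  prob = c(0.1, 0.8, 0.1))
  gAll <- cbind(g, weird)
  colnames(gAll) <- sprintf("i%02d", 1:41)
  x <- makeGeno(gAll)
  flagged <- qcReports(flagOutlierIndividuals(x, k = 3))[[1]]@params$flagged
  expect_true("i41" %in% flagged)
  out <- flagOutlierIndividuals(x, k = 3, remove = TRUE)
  expect_false("i41" %in% colnames(out))
  # homogeneous population: no flags
  xh <- makeGeno(gAll[, 1:40])
  expect_length(qcReports(flagOutlierIndividuals(xh, k = 3))[[1]]@params$flagged, 0)
  # infinite k never flags
  expect_length(qcReports(flagOutlierIndividuals(x, k = Inf))[[1]]@params$flagged, 0)
})

test_that("iterative distortion filtering converges on simulated data", {
  sim <- simulatePopulation(200, 150, 120, t = 7, h = 0.6373, seed = 21)
  out <- iterativeDistortionFilter(sim, alpha = 1e-15, passes = 3)
  Hh <- S4Vectors::metadata(out)$Hhistory
  expect_length(Hh, 4L)
  steps <- abs(diff(Hh))
  expect_true(all(diff(steps) <= 1e-12))   # non-increasing adjustment
  expect_lt(steps[3], 1e-6)                # settled by the third pass
})

test_that("QC reports serialize to tab-delimited text", {
  g <- matrix("A", 5, 4, dimnames = list(sprintf("m%d", 1:5),
                                         sprintf("i%d", 1:4)))
  g[1, ] <- NA
  x <- filterMissingness(makeGeno(g))
  path <- tempfile(fileext = ".tsv")
  writeQcReports(x, path)
  tab <- read.delim(path)
  expect_true(any(tab$type == "marker" & tab$item == "m1"))
  expect_output(show(qcReports(x)[[1]]), "missingness")
})
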