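test_that("generators are bit-identical for identical (config, seed)", {
  t1 <- simulateTimedTree(10, samplingWindow = 50, seed = 42)
  t2 <- simulateTimedTree(10, samplingWindow = 50, seed = 42)
  expect_identical(ape::write.tree(treeOf(t1)), ape::write.tree(treeOf(t2)))
  expect_identical(tipDates(t1), tipDates(t2))
  a1 <- simulateDNA(t1, kappa = 3, length = 50, seed = 7)
  a2 <- simulateDNA(t2, kappa = 3, length = 50, seed = 7)
  expect_identical(alignmentMatrix(a1), alignmentMatrix(a2))
  u1 <- simulateUTRSet(10, seed = 5)
  u2 <- simulateUTRSet(10, seed = 5)
  expect_identical(u1$truth, u2$truth)
  expect_identical(childSeed(3L, "dna"), childSeed(3L, "dna"))
  expect_false(childSeed(3L, "dna") == childSeed(3L, "codon"))
})

test_that("tree generator respects sampling modes and window", {
  iso <- simulateTimedTree(10, isochronous = TRUE, seed = 1)
  expect_equal(length(unique(tipDates(iso))), 1L)
  expect_error(fitRootToTip(iso), "isochronous")
  het <- simulateTimedTree(50, samplingWindow = 100, seed = 2)
  expect_lte(diff(range(tipDates(het))), 100)
  expect_true(isChronogram(het))
  bd <- simulateTimedTree(12, model = "birth-death", seed = 3)
  expect_equal(length(unique(tipDates(bd))), 1L)
})

test_that("coalescent root age matches Kingman theory within 3 SE", {
  Ne <- 25
  n <- 10
  ages <- vapply(seq_len(200), function(i)
    max(nodeHeights(simulateTimedTree(n, isochronous = TRUE, Ne = Ne,
                                      seed = 500 + i))), 1.0)
  theory <- 2 * Ne * (1 - 1 / n)
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - theory), 3 * se)
})

test_that("HKY generator reproduces kappa limits and base composition", {
  tt <- simulateTimedTree(8, samplingWindow = 40, Ne = 20, seed = 6)
  ## near-infinite kappa: transversions vanish
  aln <- simulateDNA(tt, kappa = 1e6, length = 400, rate = 3e-3, seed = 7)
  m <- alignmentMatrix(aln)
  isPur <- matrix(m %in% c("A", "G"), nrow(m))
  ## every column is all-purine or all-pyrimidine
  mixed <- apply(isPur, 2, function(v) length(unique(v)) > 1L)
  expect_equal(sum(mixed), 0L)
  ## kappa = 1, equal frequencies: ts/tv ratio ~ 1/2 at low divergence on pairs
  tt2 <- simulateTimedTree(40, samplingWindow = 5, Ne = 4, seed = 8)
  aln2 <- simulateDNA(tt2, kappa = 1, length = 8000, rate = 1e-3, seed = 9)
  m2 <- alignmentMatrix(aln2)
  ts <- tv <- 0
  pur <- c("A", "G")
  for (j in seq_len(ncol(m2))) {
    v <- unique(m2[, j])
    if (length(v) == 2L) {
      if (sum(v %in% pur) %in% c(0L, 2L)) ts <- ts + 1 else tv <- tv + 1
    }
  }
  expect_equal(ts / tv, 0.5, tolerance = 0.3)
  ## stationary base composition
  freqs <- c(0.4, 0.1, 0.2, 0.3)
  aln3 <- simulateDNA(tt, kappa = 3, baseFreqs = freqs, length = 3000,
                      rate = 1e-3, seed = 10)
  obs <- table(factor(alignmentMatrix(aln3), c("A", "C", "G", "T")))
  n <- sum(obs)
  for (b in 1:4) {
    se <- sqrt(freqs[b] * (1 - freqs[b]) / n) * sqrt(8)  # tips correlated
    expect_lt(abs(obs[b] / n - freqs[b]), max(5 * se, 0.03))
  }
})

test_that("codon generator matches matrix-exponential expectations", {
  ## two-taxon tree: observed codon-change fraction vs P(t) theory
  tr <- ape::read.tree(text = "(A:50,B:50);")
  tt <- timedTree(tr, c(A = 2000, B = 2000))
  rate <- 4e-3
  sim <- simulateCodon(tt, kappa = 2,
                       omegaSpec = list(p0 = 1 - 2e-9, p1 = 1e-9,
                                        omega0 = 0.3, omega2 = 1),
                       nCodons = 3000, rate = rate, seed = 13)
  cm <- codonMatrix(sim$alignment)
  pDiffObs <- mean(cm[1, ] != cm[2, ])
  Q <- codonRateMatrix(2, 0.3, rep(1 / 61, 61))
  P <- parevol:::revPmat(Q, rep(1 / 61, 61), 100 * rate)  # A-to-B path
  pDiffTheory <- 1 - mean(diag(P))
  se <- sqrt(pDiffTheory * (1 - pDiffTheory) / 3000)
  expect_lt(abs(pDiffObs - pDiffTheory), 3 * se)
})

test_that("divergent-cluster generator honors its truth labels", {
  tc <- twoClusterTree(8, 8, Ne = 20, stem = 30, seed = 3)
  cp <- clusterPair(tc$tree, tc$cluster1, tc$cluster2)
  simII <- simulateDivergentClusters(cp, theta = 1, type = "II",
                                     length = 50, seed = 14)
  m <- alignmentMatrix(simII$alignment)
  for (j in which(simII$divergent)) {
    r1 <- unique(m[tc$cluster1, j])
    r2 <- unique(m[tc$cluster2, j])
    expect_length(r1, 1L)
    expect_length(r2, 1L)
    expect_false(AA_CLASS_DEFAULT[r1] == AA_CLASS_DEFAULT[r2])
  }
})

test_that("planted coevolving pairs co-segregate perfectly by construction", {
  tt <- simulateTimedTree(12, samplingWindow = 0.001, Ne = 30, seed = 15)
  sim <- simulateCoevolvingAlignment(tt, nBackground = 10, nPlantedPairs = 2,
                                     seed = 16)
  red <- reduceAlphabet(sim$alignment)
  for (r in seq_len(nrow(sim$truth))) {
    s1 <- columnTreePattern(sim$truth$column_i[r], tt, red)
    s2 <- columnTreePattern(sim$truth$column_j[r], tt, red)
    expect_equal(parevol:::`.cpp_partition_score`(unname(s1), unname(s2)), 1.0)
  }
})

test_that("UTR generator plants exactly recoverable motifs at rate 0", {
  u <- simulateUTRSet(n = 150, sdFrequency = 0.6, naFrequency = 0.1,
                      mutationRate = 0, seed = 17)
  hits <- scanSegments(u$segments)
  detected <- hits$category[match(u$truth$strain_id, hits$strain_id)]
  expect_identical(detected, u$truth$planted)
  ## sd_frequency 0: nothing canonical/variant
  u0 <- simulateUTRSet(n = 50, sdFrequency = 0, naFrequency = 0.2, seed = 18)
  h0 <- scanSegments(u0$segments)
  expect_true(all(h0$category %in% c("absent", "NA")))
  ## detected fraction within binomial 3 SE of the planted frequency
  f <- 0.6
  n <- 150
  detFrac <- mean(detected %in% c("canonical", "variant"))
  expect_lt(abs(detFrac - f), 3 * sqrt(f * (1 - f) / n))
  ## detection decreases monotonically with mutation rate
  det <- vapply(c(0, 0.05, 0.2), function(mu) {
    uu <- simulateUTRSet(n = 150, sdFrequency = 0.6, naFrequency = 0,
                         mutationRate = mu, seed = 19)
    hh <- scanSegments(uu$segments)
    mean(hh$category %in% c("canonical", "variant"))
  }, 1.0)
  expect_true(all(diff(det) < 0))
})
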