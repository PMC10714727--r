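test_that("cluster pairs must be monophyletic, disjoint and big enough", {
  tc <- twoClusterTree(5, 5, Ne = 15, stem = 20, seed = 1)
  cp <- clusterPair(tc$tree, tc$cluster1, tc$cluster2)
  expect_length(cp$cluster1, 5L)
  mixed <- c(tc$cluster1[1:4], tc$cluster2[1])
  expect_error(clusterPair(tc$tree, mixed, tc$cluster2[2:5]),
               "monophyletic|overlap")
  expect_error(clusterPair(tc$tree, tc$cluster1[1:3], tc$cluster2),
               "at least 4")
})

test_that("Fitch counts match hand-checked and Sankoff-oracle values", {
  tc <- twoClusterTree(4, 4, Ne = 15, stem = 20, seed = 2)
  cp <- clusterPair(tc$tree, tc$cluster1, tc$cluster2)
  sub <- cp$subtree1
  ## invariant column
  m <- matrix("A", 8, 1, dimnames = list(c(tc$cluster1, tc$cluster2), NULL))
  cnts <- countSiteChanges(msaAlignment(cbind(m, m), "protein"), tc$tree, cp)
  expect_true(all(cnts$X1 == 0) && all(cnts$X2 == 0))
  ## two states split across one internal edge of the 4-taxon subtree
  below <- parevol:::tipsBelowEdge(sub)
  sz <- vapply(below, sum, 1L)
  e2 <- which(sz == 2L)[1]
  skip_if(is.na(e2))
  col <- ifelse(below[[e2]], "K", "D")
  expect_equal(parevol:::fitchCount(sub, setNames(col, sub$tip.label)), 1L)
  ## randomized columns against an independent Sankoff implementation
  set.seed(3)
  for (r in 1:50) {
    col <- sample(c("A", "D", "K", "F", "-"), ape::Ntip(sub), replace = TRUE)
    names(col) <- sub$tip.label
    expect_equal(parevol:::fitchCount(sub, col), sankoffCount(sub, col))
  }
  ## Fitch counts never exceed taxa - 1
  expect_true(all(cnts$X1 <= cnts$n1 - 1))
})

test_that("perfectly correlated counts give theta near zero", {
  set.seed(4)
  x <- rpois(300, rgamma(300, 0.5, 0.5) * 3)
  counts <- list(X1 = x, X2 = x, T1 = 3, T2 = 3, columns = seq_along(x))
  est <- suppressWarnings(estimateThetaI(counts))
  expect_lte(est$theta@theta, 0.05)
  ## likelihood at theta = 0 equals the pure shared model (nesting)
  expect_gte(est$theta@aux$lnLAlt, est$theta@aux$lnLNull - 1e-6)
})

test_that("theta-I separates theta = 0 from theta = 1 and stays in [0,1]", {
  th0 <- th1 <- numeric(6)
  for (i in seq_len(6)) {
    tc <- twoClusterTree(24, 24, Ne = 60, stem = 30, seed = i)
    cp <- clusterPair(tc$tree, tc$cluster1, tc$cluster2)
    s0 <- simulateDivergentClusters(cp, theta = 0, type = "I", length = 300,
                                    rate = 0.004, seed = 40 + i)
    s1 <- simulateDivergentClusters(cp, theta = 1, type = "I", length = 300,
                                    rate = 0.004, seed = 80 + i)
    th0[i] <- suppressWarnings(
      estimateThetaI(countSiteChanges(s0$alignment, tc$tree, cp)))$theta@theta
    th1[i] <- suppressWarnings(
      estimateThetaI(countSiteChanges(s1$alignment, tc$tree, cp)))$theta@theta
    expect_true(all(c(th0[i], th1[i]) >= 0 & c(th0[i], th1[i]) <= 1))
  }
  expect_gte(median(th1) - median(th0), 0.5)
  expect_lte(median(th0), 0.1)
})

test_that("decorrelating cluster-2 columns drives theta-I up", {
  tc <- twoClusterTree(24, 24, Ne = 60, stem = 30, seed = 9)
  cp <- clusterPair(tc$tree, tc$cluster1, tc$cluster2)
  sim <- simulateDivergentClusters(cp, theta = 0, type = "I", length = 400,
                                   rate = 0.004, seed = 10)
  cts <- countSiteChanges(sim$alignment, tc$tree, cp)
  base <- suppressWarnings(estimateThetaI(cts))$theta@theta
  shuf <- cts
  set.seed(11)
  perm <- sample(length(shuf$X2))
  shuf$X2 <- shuf$X2[perm]
  up <- suppressWarnings(estimateThetaI(shuf))$theta@theta
  expect_gt(up, base + 0.3)
})

test_that("theta-II classifies planted constant-but-different columns", {
  tc <- twoClusterTree(10, 10, Ne = 20, stem = 40, seed = 5)
  cp <- clusterPair(tc$tree, tc$cluster1, tc$cluster2)
  th <- numeric(10)
  for (i in seq_len(10)) {
    sim <- simulateDivergentClusters(cp, theta = 0.2, type = "II",
                                     shapeShared = 0.5, meanRate = 0.6,
                                     rate = 0.02, length = 400,
                                     seed = 300 + i)
    th[i] <- estimateThetaII(sim$alignment, tc$tree, cp)$theta@theta
  }
  expect_gte(median(th), 0.1)
  expect_lte(median(th), 0.3)
  ## identical consensus everywhere -> theta ~ 0
  sim0 <- simulateDivergentClusters(cp, theta = 0, type = "II",
                                    meanRate = 0.4, rate = 0.02, length = 400,
                                    seed = 7)
  expect_lte(estimateThetaII(sim0$alignment, tc$tree, cp)$theta@theta, 0.05)
  ## all columns variable -> error
  set.seed(8)
  m <- matrix(sample(names(AA_CLASS_DEFAULT), 20 * 60, TRUE), 20,
              dimnames = list(c(tc$cluster1, tc$cluster2), NULL))
  expect_error(estimateThetaII(msaAlignment(m, "protein"), tc$tree, cp),
               "undefined")
})

test_that("site flagging respects the cutoff and coordinate map", {
  post <- new("SitePosterior", qk = c(0.99, 0.97, 0.981), cutoff = 0.98,
              flagged = which(c(0.99, 0.97, 0.981) > 0.98))
  rep1 <- flagDivergentSites(post)
  expect_equal(rep1$column[rep1$flagged], c(1L, 3L))
  ## empty flag set below the cutoff
  post2 <- new("SitePosterior", qk = c(0.5, 0.2), cutoff = 0.98,
               flagged = integer())
  expect_equal(sum(flagDivergentSites(post2)$flagged), 0L)
  ## coordinate remap against a hand-built gapped reference
  aln <- msaAlignment(c(ref = "A-CD-E", other = "AKCDFE"), "protein")
  cmap <- referenceCoordinateMap(aln, "ref")
  expect_equal(cmap, c(1L, NA, 2L, 3L, NA, 4L))
  rep3 <- flagDivergentSites(post, coordinateMap = cmap, columns = c(2, 3, 4))
  expect_equal(rep3$refPosition, c(NA, 2L, 3L))
})

test_that("qk posteriors stay in [0,1] and zero counts error out", {
  counts <- list(X1 = rep(0L, 60), X2 = rep(0L, 60), T1 = 2, T2 = 2,
                 columns = 1:60)
  expect_error(estimateThetaI(counts), "degenerate")
})
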