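## brute-force mixture likelihood on a tiny instance: enumerate internal-node
## states with explicit matrix exponentials, fully independent of the pruning
## code
bruteForceBranchSiteLnL <- function(aln, tr, scale, foreground,
                                    p0, p1, w0, w2, kappa) {
  skip_if_not_installed("Matrix")
  pi <- rep(1 / 61, 61)
  cods <- parevol:::senseCodons()
  aas <- codonAminoAcids()
  nt <- c("A", "C", "G", "T")
  spl <- do.call(rbind, strsplit(cods, ""))
  buildQ <- function(om) {
    Q <- matrix(0, 61, 61)
    Q1 <- matrix(0, 61, 61)
    for (i in 1:61) for (j in 1:61) {
      if (i == j) next
      diffs <- which(spl[i, ] != spl[j, ])
      if (length(diffs) != 1L) next
      a <- spl[i, diffs]; b <- spl[j, diffs]
      ts <- (a == "A" && b == "G") || (a == "G" && b == "A") ||
        (a == "C" && b == "T") || (a == "T" && b == "C")
      base <- if (ts) kappa else 1
      Q1[i, j] <- base * pi[j]
      Q[i, j] <- base * pi[j] * if (aas[i] != aas[j]) om else 1
    }
    diag(Q) <- -rowSums(Q)
    diag(Q1) <- -rowSums(Q1)
    Q / sum(pi * -diag(Q1))
  }
  st <- match(gsub("U", "T", codonMatrix(aln)), cods)
  st <- matrix(st, nrow(codonMatrix(aln)),
               dimnames = dimnames(codonMatrix(aln)))
  st <- st[tr$tip.label, , drop = FALSE]
  wts <- parevol:::modelAWeights(p0, p1)
  omB <- c(w0, 1, w0, 1)
  omF <- c(w0, 1, w2, w2)
  fg <- seq_len(nrow(tr$edge)) %in% foreground
  ntip <- ape::Ntip(tr)
  nint <- tr$Nnode
  grid <- as.matrix(expand.grid(rep(list(1:61), nint)))
  ll <- 0
  for (site in seq_len(ncol(st))) {
    tot <- 0
    for (cl in 1:4) {
      Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
        as.matrix(Matrix::expm(buildQ(if (fg[e]) omF[cl] else omB[cl]) *
                                 tr$edge.length[e] * scale)))
      v <- 0
      for (g in seq_len(nrow(grid))) {
        stt <- c(st[, site], grid[g, ])
        pr <- pi[stt[ntip + 1L]]
        for (e in seq_len(nrow(tr$edge)))
          pr <- pr * Ps[[e]][stt[tr$edge[e, 1]], stt[tr$edge[e, 2]]]
        v <- v + pr
      }
      tot <- tot + wts[cl] * v
    }
    ll <- ll + log(tot)
  }
  ll
}

test_that("codon mixture likelihood matches brute-force enumeration", {
  tt <- threeTipTree()
  tr <- treeOf(tt)
  sim <- simulateCodon(tt, kappa = 3,
                       omegaSpec = list(p0 = .4, p1 = .3, omega0 = .2,
                                        omega2 = 4),
                       foreground = 1L, nCodons = 8, rate = 5e-3, seed = 9)
  st <- parevol:::codonStates(sim$alignment)[tr$tip.label, ]
  llFast <- parevol:::branchSiteLogLik(
    st, rep(1, ncol(st)), tr, tr$edge.length * 5e-3, 1L,
    p0 = .4, p1 = .3, omega0 = .2, omega2 = 4, kappa = 3, pi = rep(1 / 61, 61))
  llBrute <- bruteForceBranchSiteLnL(sim$alignment, tr, 5e-3, 1L,
                                     .4, .3, .2, 4, 3)
  expect_lt(abs(llFast - llBrute), 1e-8)
})

test_that("pinning omega2 = 1 in the alternative reproduces the null lnL", {
  tt <- simulateTimedTree(6, samplingWindow = 50, Ne = 20, seed = 4)
  tr <- treeOf(tt)
  sim <- simulateCodon(tt, kappa = 2,
                       omegaSpec = list(p0 = .5, p1 = .3, omega0 = .1,
                                        omega2 = 3),
                       foreground = 2L, nCodons = 60, rate = 4e-3, seed = 5)
  st <- parevol:::codonStates(sim$alignment)[tr$tip.label, ]
  w <- rep(1, ncol(st))
  pi <- rep(1 / 61, 61)
  llA <- parevol:::branchSiteLogLik(st, w, tr, tr$edge.length * 4e-3, 2L,
                                    .5, .3, .1, 1, 2, pi)
  llNull <- parevol:::branchSiteLogLik(st, w, tr, tr$edge.length * 4e-3, 2L,
                                       .5, .3, .1, 1 + 1e-12, 2, pi)
  expect_lt(abs(llA - llNull), 1e-6)
})

test_that("codon likelihood is invariant to taxon order", {
  tt <- simulateTimedTree(6, samplingWindow = 50, Ne = 20, seed = 11)
  tr <- treeOf(tt)
  sim <- simulateCodon(tt, kappa = 2,
                       omegaSpec = list(p0 = .6, p1 = .2, omega0 = .15,
                                        omega2 = 2),
                       foreground = 1L, nCodons = 50, rate = 4e-3, seed = 12)
  st <- parevol:::codonStates(sim$alignment)[tr$tip.label, ]
  pi <- rep(1 / 61, 61)
  ll1 <- parevol:::branchSiteLogLik(st, rep(1, ncol(st)), tr,
                                    tr$edge.length * 4e-3, 1L,
                                    .6, .2, .15, 2, 2, pi)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  st2 <- st[tr2$tip.label, ]
  ## map edges of tr2 back: same topology, so foreground = matching child clade
  ch1 <- tr$edge[1, 2]
  below1 <- parevol:::tipsBelowEdge(tr)[[1]]
  fg2 <- which(vapply(parevol:::tipsBelowEdge(tr2), function(b)
    identical(sort(tr2$tip.label[b]), sort(tr$tip.label[below1])), TRUE))[1]
  ll2 <- parevol:::branchSiteLogLik(st2, rep(1, ncol(st2)), tr2,
                                    tr2$edge.length * 4e-3, fg2,
                                    .6, .2, .15, 2, 2, pi)
  expect_lt(abs(ll1 - ll2), 1e-8)
})

test_that("likelihood-ratio test follows the chi-square reference", {
  expect_equal(lrt(-10, -10)$statistic, 0)
  expect_equal(lrt(-10, -10)$pValue, 1)
  res <- lrt(-8.07927, -10, df = 1)   # delta lnL = 1.92073
  expect_equal(res$pValue, 0.05, tolerance = 1e-4)
  expect_error(lrt(-10.5, -10), "below the null")
})

test_that("branch-site fit recovers strong positive selection", {
  tt <- simulateTimedTree(8, samplingWindow = 60, Ne = 25, seed = 11)
  tr <- treeOf(tt)
  iedges <- which(tr$edge[, 2] > ape::Ntip(tr))
  fg <- iedges[which.max(tr$edge.length[iedges])]
  sim <- simulateCodon(tt, kappa = 2,
                       omegaSpec = list(p0 = .5, p1 = .3, omega0 = .1,
                                        omega2 = 6),
                       foreground = fg, nCodons = 300, rate = 5e-3, seed = 21)
  f <- fitBranchSiteModel(sim$alignment, tt, fg, nRestarts = 2)
  expect_s4_class(f, "BranchSiteFit")
  expect_gt(f@params$omega2, 1)
  expect_lt(f@pValue, 0.05)
  expect_true(f@significant)
  expect_gte(f@lnLAlt, f@lnLNull - 1e-6)
  ## foreground contract checks
  expect_error(fitBranchSiteModel(sim$alignment, tt, integer()), "non-empty")
  expect_error(fitBranchSiteModel(sim$alignment, tt, 999L), "invalid")
})

test_that("omega = 0 simulations produce no amino-acid change", {
  tt <- simulateTimedTree(6, samplingWindow = 40, Ne = 20, seed = 31)
  sim <- simulateCodon(tt, kappa = 2,
                       omegaSpec = list(p0 = 1 - 2e-9, p1 = 1e-9, omega0 = 0,
                                        omega2 = 1),
                       foreground = integer(), nCodons = 100, rate = 5e-3,
                       seed = 32)
  cm <- codonMatrix(sim$alignment)
  aas <- codonAminoAcids()
  prot <- matrix(aas[gsub("U", "T", cm)], nrow(cm))
  expect_true(all(apply(prot, 2, function(v) length(unique(v)) == 1L)))
})

test_that("adaptive divergence series follows sum(omega2)/kappa exactly", {
  ## fixture: 170-year tree, three significant branches in known windows
  deep <- ape::read.tree(text = "((A:30,B:30):140,(C:80,D:160):10);")
  td <- timedTree(deep, c(A = 2000, B = 2000, C = 1920, D = 2000))
  part <- assignEpochs(td, 3, 50)
  h <- nodeHeights(td)
  tr <- treeOf(td)
  mid <- (h[tr$edge[, 1]] + h[tr$edge[, 2]]) / 2
  ## single significant branch omega2 = 4 with kappa = 2 in its epoch -> AD 2
  tipA <- which(tr$edge[, 2] == which(tr$tip.label == "A"))   # heights 0..30
  fits1 <- data.frame(edge = tipA, omega2 = 4, pValue = 0.01)
  kap <- data.frame(epoch = 1:3, kappa = c(8, 4, 2))
  ad1 <- adaptiveDivergence(fits1, td, part, kap)
  w1 <- which(ad1$windowEnd == 2000)
  expect_equal(ad1$AD[w1], 4 / 2)
  expect_true(all(ad1$AD[-w1] == 0))

  ## three significant branches over three windows, hand-assigned midpoints:
  ## edge to A spans heights 0..30 (mid 15, window 1, epoch 3);
  ## edge to D spans 0..160 (mid 80, window 2, epoch 2);
  ## edge to C spans 80..160 (mid 120, window 3, epoch 1)
  tipC <- which(tr$edge[, 2] == which(tr$tip.label == "C"))
  tipD <- which(tr$edge[, 2] == which(tr$tip.label == "D"))
  fits3 <- data.frame(edge = c(tipA, tipC, tipD),
                      omega2 = c(2, 3, 5), pValue = 0.01)
  ad3 <- adaptiveDivergence(fits3, td, part, kap)
  expect_equal(ad3$AD[ad3$windowEnd == 2000], 2 / 2)
  expect_equal(ad3$AD[ad3$windowEnd == 1950], 5 / 4)
  expect_equal(ad3$AD[ad3$windowEnd == 1900], 3 / 8)
  ## no significant branches -> all-zero series
  fits0 <- data.frame(edge = tipA, omega2 = 4, pValue = 0.5)
  expect_true(all(adaptiveDivergence(fits0, td, part, kap)$AD == 0))
  ## doubling kappa halves AD
  kap2 <- data.frame(epoch = 1:3, kappa = 2 * kap$kappa)
  expect_equal(adaptiveDivergence(fits3, td, part, kap2)$AD, ad3$AD / 2)
  ## missing kappa for a needed epoch errors
  kapNA <- data.frame(epoch = 1:3, kappa = c(8, NA, 2))
  expect_error(adaptiveDivergence(fits3, td, part, kapNA), "kappa missing")
})
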