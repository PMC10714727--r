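test_that("root-to-tip regression is exact on noise-free clocklike trees", {
  tt <- simulateTimedTree(15, samplingWindow = 60, Ne = 25, seed = 7)
  r <- 2e-3
  div <- divergenceTree(tt, r)
  for (rooting in c("best-r2", "residual-mean-squared")) {
    cf <- fitRootToTip(div, rooting)
    expect_lt(abs(cf@rate - r), 1e-9)
    expect_lt(abs(cf@rSquared - 1), 1e-9)
    trueRoot <- latestTipDate(tt) - max(nodeHeights(tt))
    expect_lt(abs(cf@tmrca - trueRoot), 1e-6)
  }
})

test_that("root-to-tip regression slope is covered by its own OLS interval", {
  hits <- 0L
  nrep <- 60L
  r <- 2e-3
  for (i in seq_len(nrep)) {
    tt <- simulateTimedTree(20, samplingWindow = 80, Ne = 25, seed = 100 + i)
    tr <- treeOf(tt)
    tr$edge.length <- tr$edge.length * r
    set.seed(i)
    tipEdges <- which(tr$edge[, 2] <= ape::Ntip(tr))
    tr$edge.length[tipEdges] <- pmax(
      tr$edge.length[tipEdges] + rnorm(length(tipEdges), 0, 0.004), 0)
    div <- timedTree(tr, tipDates(tt))
    cf <- fitRootToTip(div, "fixed")
    ## OLS closed-form 95% CI as the oracle
    d <- ape::dist.nodes(tr)[ape::Ntip(tr) + 1L, seq_len(ape::Ntip(tr))]
    fit <- lm(d ~ unname(tipDates(div)))
    ci <- suppressWarnings(confint(fit))[2, ]
    expect_equal(unname(coef(fit)[2]), cf@rate, tolerance = 1e-12)
    if (r >= ci[1] && r <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, round(0.85 * nrep))
})

test_that("isochronous tips raise the documented error", {
  tt <- simulateTimedTree(8, isochronous = TRUE, seed = 2)
  expect_error(fitRootToTip(tt), "isochronous tips: temporal signal undefined")
})

test_that("root-to-tip fit is invariant to tip order and joint rescaling", {
  tt <- simulateTimedTree(12, samplingWindow = 50, Ne = 20, seed = 9)
  div <- divergenceTree(tt, 3e-3)
  cf <- fitRootToTip(div)
  ## tip reordering
  tr2 <- ape::rotateConstr(treeOf(div), rev(treeOf(div)$tip.label))
  cf2 <- fitRootToTip(timedTree(tr2, tipDates(div)))
  expect_equal(cf@rate, cf2@rate, tolerance = 1e-9)
  expect_equal(cf@rSquared, cf2@rSquared, tolerance = 1e-9)
  ## scaling distances by c scales the slope by c
  div3 <- divergenceTree(tt, 6e-3)
  cf3 <- fitRootToTip(div3)
  expect_equal(cf3@rate / cf@rate, 2, tolerance = 1e-9)
  expect_equal(cf3@tmrca, cf@tmrca, tolerance = 1e-6)
})

test_that("PS and SS are exact for beta-independent likelihoods", {
  tr <- powerPosteriorTrace(betaLadder(10), replicate(10, rep(-5, 40),
                                                      simplify = FALSE))
  expect_equal(logML(pathSamplingLogML(tr)), -5, tolerance = 1e-12)
  expect_equal(logML(steppingStoneLogML(tr)), -5, tolerance = 1e-12)
  single <- new("PowerPosteriorTrace", betas = c(0, 1),
                samples = list(rep(-5, 3), rep(-5, 3)))
  expect_error(powerPosteriorTrace(0.5, list(rep(-5, 3))), "2 rungs")
})

test_that("PS and SS hit the conjugate-normal analytic value within 3 SE", {
  y <- conjData(seed = 1)
  mod <- conjugateNormalModel(sigma = 1, mu0 = 0, tau0 = 3)
  exact <- mod$exactLogML(y)
  tr <- conjugateNormalTrace(mod, y, betaLadder(50), 1000, seed = 2)
  ps <- pathSamplingLogML(tr)
  ss <- steppingStoneLogML(tr)
  expect_lt(abs(logML(ps) - exact), 3 * mcSE(ps))
  expect_lt(abs(logML(ss) - exact), 3 * mcSE(ss))
  ## cross-estimator consistency
  expect_lt(abs(logML(ps) - logML(ss)), 3 * (mcSE(ps) + mcSE(ss)))
})

test_that("doubling samples keeps the PS expectation and shrinks mc_se", {
  y <- conjData(seed = 3)
  mod <- conjugateNormalModel()
  tr1 <- conjugateNormalTrace(mod, y, betaLadder(40), 500, seed = 4)
  tr2 <- conjugateNormalTrace(mod, y, betaLadder(40), 1000, seed = 5)
  ps1 <- pathSamplingLogML(tr1)
  ps2 <- pathSamplingLogML(tr2)
  expect_lt(abs(logML(ps1) - logML(ps2)), 3 * (mcSE(ps1) + mcSE(ps2)))
  expect_lt(mcSE(ps2), mcSE(ps1))
  expect_equal(mcSE(ps2) / mcSE(ps1), 1 / sqrt(2), tolerance = 0.35)
})

test_that("table1 Bayes-factor arithmetic matches the printed values", {
  tab <- table1Rows()
  for (i in seq_len(nrow(tab))) {
    cmp <- betsCompare(tab$het[i], tab$iso[i], convention = "table1")
    expect_lt(abs(cmp@bayesFactor - tab$bf[i]), 1e-3)
    expect_identical(cmp@favored, "heterochronous")
  }
  ## log-bf convention flips the sign
  cmp2 <- betsCompare(tab$het[1], tab$iso[1], convention = "log-bf")
  expect_equal(cmp2@bayesFactor, -(tab$iso[1] - tab$het[1]), tolerance = 1e-9)
  ## equal log-MLs are inconclusive
  eq <- betsCompare(-10, -10)
  expect_equal(eq@bayesFactor, 0)
  expect_identical(eq@favored, "inconclusive")
})

test_that("a {0,1} ladder degrades gracefully", {
  set.seed(6)
  samples <- list(rnorm(2000, -8, 3), rnorm(2000, -5, 0.5))
  tr <- powerPosteriorTrace(c(0, 1), samples)
  ps <- pathSamplingLogML(tr)
  expect_true(is.finite(logML(ps)))
  expect_gt(mcSE(ps), 0)
})

test_that("toy BETS favors heterochronous data and not permuted dates", {
  mod <- strictClockRegressionModel()
  bfSig <- bfPerm <- numeric(6)
  for (s in seq_len(6)) {
    set.seed(s)
    n <- 30
    t <- runif(n, 1960, 2020)
    d <- 0.005 * (t - 1940) + rnorm(n, 0, 0.02)
    iso <- list(d = d, t = rep(max(t), n))
    bfSig[s] <- runBetsToy(mod, list(d = d, t = t), iso, ladderSize = 16,
                           samplesPerRung = 400, seed = s,
                           estimator = "SS")$comparison@bayesFactor
    set.seed(1000 + s)
    bfPerm[s] <- runBetsToy(mod, list(d = d, t = sample(t)), iso,
                            ladderSize = 16, samplesPerRung = 400,
                            seed = 100 + s,
                            estimator = "SS")$comparison@bayesFactor
  }
  expect_gte(sum(bfSig > 3), 5L)
  expect_gte(sum(abs(bfPerm) < 3), 5L)
})
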