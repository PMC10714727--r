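## Temporal-signal assessment: root-to-tip regression, path-sampling /
## stepping-stone log-marginal-likelihood estimators, and Bayes-factor
## comparison of heterochronous vs isochronous models.

## Run expr under a temporary RNG state so internal resampling (bootstrap
## standard errors) does not disturb the caller's stream.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## ---------------------------------------------------------------------------
## Root-to-tip regression
## ---------------------------------------------------------------------------

#' Root-to-tip regression against sampling dates
#'
#' Ordinary least squares of root-to-tip path length on tip date, with the
#' root position chosen over every point of every branch to optimize the
#' rooting criterion. The slope estimates the substitution rate (distance
#' units per year) and the x-intercept the time of the most recent common
#' ancestor (tMRCA, calendar year).
#'
#' Along any branch the root-to-tip distances are linear in the root position,
#' so both criteria (maximal R-squared; minimal residual mean square) have
#' closed-form per-branch optima; these are evaluated exactly and the best
#' branch wins, ties broken by the smallest edge index.
#'
#' @param x a \code{TimedTree}.
#' @param rooting \code{"best-r2"}, \code{"residual-mean-squared"} or
#'   \code{"fixed"} (keep the current root).
#' @return a \code{ClockFit}.
#' @export
fitRootToTip <- function(x, rooting = c("best-r2", "residual-mean-squared",
                                        "fixed")) {
  rooting <- match.arg(rooting)
  tr <- treeOf(x)
  ntip <- ape::Ntip(tr)
  if (ntip < 3L) stop("need at least 3 tips for root-to-tip regression")
  dates <- tipDates(x)
  if (length(unique(dates)) < 2L)
    stop("isochronous tips: temporal signal undefined")
  tvec <- unname(dates)
  tc <- tvec - mean(tvec)
  Vt <- sum(tc^2)

  D <- ape::dist.nodes(tr)
  root <- ntip + 1L

  fitAt <- function(d) {
    fit <- lm(d ~ tvec)
    res <- residuals(fit)
    ss_tot <- sum((d - mean(d))^2)
    r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = max(0, min(1, r2)), res = setNames(res, tr$tip.label))
  }

  if (rooting == "fixed") {
    d <- D[root, seq_len(ntip)]
    f <- fitAt(d)
    bestEdge <- 0L
  } else {
    below <- tipsBelowEdge(tr)   # list over edges: logical of tips below child
    bestCrit <- -Inf
    bestEdge <- 0L
    bestX <- 0
    for (e in seq_len(nrow(tr$edge))) {
      u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]; L <- tr$edge.length[e]
      under <- below[[e]]
      ## distance from a point at distance x above v (toward u):
      ##   tips below v: a_i + x;   others: b_i + (L - x)
      c0 <- ifelse(under, D[v, seq_len(ntip)], D[u, seq_len(ntip)] + L)
      s <- ifelse(under, 1, -1)
      cc <- c0 - mean(c0); sc <- s - mean(s)
      A <- sum(cc * tc); B <- sum(sc * tc)
      C <- sum(cc^2); Dq <- sum(cc * sc); E <- sum(sc^2)
      cand <- c(0, L)
      if (rooting == "best-r2") {
        den <- B * Dq - A * E
        if (abs(den) > 1e-300) cand <- c(cand, (A * Dq - B * C) / den)
      } else {
        den <- E - B^2 / Vt
        if (abs(den) > 1e-300) cand <- c(cand, (A * B / Vt - Dq) / den)
      }
      cand <- unique(pmin(pmax(cand, 0), L))
      for (xx in cand) {
        num <- (A + B * xx)^2
        vard <- C + 2 * Dq * xx + E * xx^2
        crit <- if (rooting == "best-r2") {
          if (vard <= 0) -Inf else num / (vard * Vt)
        } else {
          -(vard - num / Vt)  # maximize negative RSS
        }
        if (crit > bestCrit + 1e-12) {
          bestCrit <- crit; bestEdge <- e; bestX <- xx
        }
      }
    }
    e <- bestEdge
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]; L <- tr$edge.length[e]
    under <- below[[e]]
    d <- ifelse(under, D[v, seq_len(ntip)] + bestX,
                D[u, seq_len(ntip)] + (L - bestX))
    f <- fitAt(d)
  }

  tmrca <- if (is.finite(f$slope) && f$slope != 0) -f$intercept / f$slope else NA_real_
  new("ClockFit", rate = f$slope, tmrca = tmrca, rSquared = f$r2,
      intercept = f$intercept, residuals = f$res, rooting = rooting,
      rootEdge = as.integer(bestEdge))
}

## logical vector per edge: which tips are below (descend from) the edge's
## child node
tipsBelowEdge <- function(tr) {
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  ord <- rev(ape::postorder(tr))   # we need children before parents: postorder
  for (e in ape::postorder(tr)) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  lapply(seq_len(nrow(tr$edge)), function(e) {
    out <- logical(ntip)
    out[desc[[tr$edge[e, 2L]]]] <- TRUE
    out
  })
}

## ---------------------------------------------------------------------------
## Marginal-likelihood estimators
## ---------------------------------------------------------------------------

#' Construct a power-posterior trace
#'
#' @param betas increasing ladder in [0,1] including 0 and 1.
#' @param samples list of numeric log-likelihood sample vectors, one per rung.
#' @export
powerPosteriorTrace <- function(betas, samples) {
  new("PowerPosteriorTrace", betas = as.numeric(betas), samples = samples)
}

#' Read a power-posterior trace from TSV
#'
#' Columns: \code{beta}, \code{sample_index}, \code{log_likelihood}.
#' @param path TSV file.
#' @export
readPowerPosteriorTrace <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("beta", "log_likelihood")
  if (!all(need %in% names(tab)))
    stop("trace must have columns beta and log_likelihood")
  b <- sort(unique(tab$beta))
  powerPosteriorTrace(b, lapply(b, function(bb) tab$log_likelihood[tab$beta == bb]))
}

## block-bootstrap variance of a statistic of one rung's samples
blockBootVar <- function(x, stat, block = 50L, B = 200L) {
  n <- length(x)
  if (n <= block) return(0)
  nb <- ceiling(n / block)
  starts_max <- n - block + 1L
  reps <- vapply(seq_len(B), function(b) {
    st <- sample.int(starts_max, nb, replace = TRUE)
    idx <- as.vector(outer(0:(block - 1L), st, "+"))[seq_len(n)]
    stat(x[idx])
  }, 1.0)
  var(reps)
}

#' Path-sampling estimate of the log marginal likelihood
#'
#' Trapezoidal quadrature over the power ladder of the per-rung mean
#' log-likelihood. The Monte-Carlo standard error combines per-rung
#' block-bootstrap variances of the rung means through the quadrature weights.
#'
#' @param trace a \code{PowerPosteriorTrace}.
#' @param block block length for the bootstrap (consecutive samples).
#' @param B bootstrap replicates.
#' @param bootSeed internal seed for the bootstrap (does not touch the
#'   caller's RNG stream).
#' @return a \code{MarginalLikelihoodEstimate}.
#' @export
pathSamplingLogML <- function(trace, block = 50L, B = 200L, bootSeed = 1L) {
  b <- trace@betas
  if (length(b) < 2L) stop("path sampling needs at least 2 rungs")
  means <- vapply(trace@samples, mean, 1.0)
  db <- diff(b)
  w <- numeric(length(b))
  w[1] <- db[1] / 2
  w[length(b)] <- db[length(db)] / 2
  if (length(b) > 2L)
    w[2:(length(b) - 1L)] <- (db[-length(db)] + db[-1]) / 2
  logml <- sum(w * means)
  vs <- withLocalSeed(bootSeed, vapply(trace@samples, function(x)
    blockBootVar(x, mean, block = block, B = B), 1.0))
  new("MarginalLikelihoodEstimate", method = "PS", logML = logml,
      mcSE = sqrt(sum(w^2 * vs)))
}

logMeanExp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' For each adjacent rung pair (beta_k, beta_k+1) the ratio is estimated by
#' importance sampling from the lower rung:
#' log r_k = logmeanexp((beta_k+1 - beta_k) * ll_i) over samples i of rung k,
#' stabilized by the max. The estimate is the sum of the log ratios.
#'
#' @inheritParams pathSamplingLogML
#' @return a \code{MarginalLikelihoodEstimate}.
#' @export
steppingStoneLogML <- function(trace, block = 50L, B = 200L, bootSeed = 1L) {
  b <- trace@betas
  if (length(b) < 2L) stop("stepping stone needs at least 2 rungs")
  K <- length(b) - 1L
  contrib <- numeric(K)
  vs <- numeric(K)
  withLocalSeed(bootSeed, {
    for (k in seq_len(K)) {
      db <- b[k + 1L] - b[k]
      x <- trace@samples[[k]]
      contrib[k] <- logMeanExp(db * x)
      vs[k] <- blockBootVar(x, function(z) logMeanExp(db * z),
                            block = block, B = B)
    }
  })
  new("MarginalLikelihoodEstimate", method = "SS", logML = sum(contrib),
      mcSE = sqrt(sum(vs)))
}

## ---------------------------------------------------------------------------
## Bayes-factor comparison
## ---------------------------------------------------------------------------

#' Compare heterochronous and isochronous log marginal likelihoods
#'
#' Two orientations of the log-scale Bayes factor are exposed. Under
#' \code{"table1"} the statistic is \code{logmlIso - logmlHet} (the
#' orientation that reproduces published BETS tables in which positive values
#' accompany support for the heterochronous model); under \code{"log-bf"} it
#' is \code{logmlHet - logmlIso}. Under either convention a value above
#' \code{threshold} favors the heterochronous model and below
#' \code{-threshold} the isochronous one; otherwise the comparison is
#' inconclusive.
#'
#' @param logmlHet,logmlIso log marginal likelihoods (finite).
#' @param convention \code{"table1"} or \code{"log-bf"}.
#' @param threshold decision threshold (default 3).
#' @return a \code{BetsComparison}.
#' @export
betsCompare <- function(logmlHet, logmlIso,
                        convention = c("table1", "log-bf"), threshold = 3) {
  convention <- match.arg(convention)
  stopifnot(is.finite(logmlHet), is.finite(logmlIso))
  bf <- if (convention == "table1") logmlIso - logmlHet else logmlHet - logmlIso
  favored <- if (bf > threshold) "heterochronous"
             else if (bf < -threshold) "isochronous"
             else "inconclusive"
  new("BetsComparison", logMLHet = logmlHet, logMLIso = logmlIso,
      bayesFactor = bf, favored = favored, convention = convention,
      threshold = threshold)
}

## ---------------------------------------------------------------------------
## Desk-scale BETS harness
## ---------------------------------------------------------------------------

#' Power ladder with Beta-quantile spacing
#'
#' beta_k = ((k-1)/(K-1))^(1/shape), concentrating rungs near 0 where the
#' path-sampling integrand changes fastest.
#'
#' @param K number of rungs (>= 2).
#' @param shape Beta(shape, 1) quantile exponent (default 0.3).
#' @export
betaLadder <- function(K = 50L, shape = 0.3) {
  stopifnot(K >= 2L)
  (seq(0, 1, length.out = K))^(1 / shape)
}

#' Conjugate normal test model
#'
#' iid observations with known variance and a normal prior on the mean; its
#' log marginal likelihood has a closed form, making it the standard oracle
#' for marginal-likelihood estimators.
#'
#' @param sigma known observation SD.
#' @param mu0,tau0 prior mean and SD of the unknown mean.
#' @return model spec list (logLik, logPrior, init, proposalSD, exactLogML,
#'   exactRungSampler).
#' @export
conjugateNormalModel <- function(sigma = 1, mu0 = 0, tau0 = 3) {
  list(
    npar = 1L,
    logLik = function(par, data) sum(dnorm(data, par[1], sigma, log = TRUE)),
    logPrior = function(par) dnorm(par[1], mu0, tau0, log = TRUE),
    init = function(data) mu0,
    proposalSD = function(data) max(sd(data) / sqrt(length(data)), tau0 / 10),
    ## closed-form log marginal likelihood: y ~ MVN(mu0, sigma^2 I + tau0^2 J)
    exactLogML = function(data) {
      n <- length(data)
      e <- data - mu0
      ldet <- n * log(sigma^2) + log1p(n * tau0^2 / sigma^2)
      quad <- (sum(e^2) - (tau0^2 / sigma^2) * sum(e)^2 /
                 (1 + n * tau0^2 / sigma^2)) / sigma^2
      -0.5 * (n * log(2 * pi) + ldet + quad)
    },
    ## exact draw from the beta-tempered posterior of the mean
    exactRungSampler = function(data, beta, nSamples) {
      n <- length(data)
      prec <- 1 / tau0^2 + beta * n / sigma^2
      m <- (mu0 / tau0^2 + beta * sum(data) / sigma^2) / prec
      rnorm(nSamples, m, sqrt(1 / prec))
    }
  )
}

#' Strict-clock regression test model
#'
#' Desk-scale stand-in for a dated-tip analysis: root-to-tip distances d_i
#' are modeled as N(a + rate * (t_i - max(t)), sd^2) -- a clock regression
#' anchored at the latest sampling date, with a free divergence level a,
#' a non-negative rate (exponential prior, so the model can collapse to a
#' no-clock constant-mean fit) and noise sd. With isochronous dates the rate
#' drops out of the likelihood entirely, which is what gives the
#' heterochronous/isochronous contrast its power; the implied root year is
#' max(t) - a / rate.
#'
#' @param rateMean mean of the exponential prior on the rate (default 0.003
#'   per year).
#' @param aMean,aSD normal prior on the divergence level at the latest date.
#' @param sdMeanLog,sdSDLog lognormal prior on the noise SD.
#' @return model spec list; data must be \code{list(d = , t = )}.
#' @export
strictClockRegressionModel <- function(rateMean = 0.003,
                                       aMean = 0, aSD = 1,
                                       sdMeanLog = log(0.05), sdSDLog = 0.75) {
  list(
    npar = 3L,
    logLik = function(par, data) {
      rate <- exp(par[1]); a <- par[2]; s <- exp(par[3])
      sum(dnorm(data$d, a + rate * (data$t - max(data$t)), s, log = TRUE))
    },
    logPrior = function(par) {
      ## exponential prior on the rate, sampled on the log scale (Jacobian)
      rate <- exp(par[1])
      dexp(rate, 1 / rateMean, log = TRUE) + par[1] +
        dnorm(par[2], aMean, aSD, log = TRUE) +
        dnorm(par[3], sdMeanLog, sdSDLog, log = TRUE)
    },
    init = function(data) {
      ## ordinary least squares, falling back to the prior for isochronous data
      if (length(unique(data$t)) > 1L) {
        fit <- lm(data$d ~ I(data$t - max(data$t)))
        sl <- unname(coef(fit)[2]); ic <- unname(coef(fit)[1])
        s <- max(sd(residuals(fit)), 1e-4)
        if (is.finite(sl) && sl > 1e-8) return(c(log(sl), ic, log(s)))
      }
      c(log(rateMean) - 2, mean(data$d), log(max(sd(data$d), 1e-4)))
    },
    proposalSD = function(data) c(0.25, max(sd(data$d) / 2, 0.01), 0.25)
  )
}

## effective sample size from the autocorrelation sum (initial positive
## sequence)
essOf <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Power-posterior sampling for a desk-scale model
#'
#' Random-walk Metropolis at each rung of the ladder, targeting
#' prior x likelihood^beta; returns the trace of log-likelihood values.
#'
#' @param model a model spec (see \code{conjugateNormalModel},
#'   \code{strictClockRegressionModel}).
#' @param data model data.
#' @param betas power ladder.
#' @param samplesPerRung retained samples per rung.
#' @param burnin discarded iterations per rung.
#' @param thin keep every thin-th iteration.
#' @param seed RNG seed.
#' @return list(trace = PowerPosteriorTrace, ess = per-rung ESS,
#'   warnings = character()).
#' @export
powerPosteriorSample <- function(model, data, betas = betaLadder(20L),
                                 samplesPerRung = 500L, burnin = 200L,
                                 thin = 1L, seed = 1L) {
  set.seed(seed)
  K <- length(betas)
  samples <- vector("list", K)
  par <- model$init(data)
  psd0 <- model$proposalSD(data)
  npar <- model$npar
  ess <- numeric(K)
  ## rungs are visited from beta = 1 down to 0, each chain warm-started from
  ## the previous rung; proposals adapt toward ~30% acceptance during burn-in
  for (k in rev(seq_len(K))) {
    beta <- betas[k]
    psd <- psd0
    ll <- model$logLik(par, data)
    lp <- model$logPrior(par)
    niter <- burnin + samplesPerRung * thin
    keep <- numeric(samplesPerRung)
    kept <- 0L
    acc <- 0L
    win <- 0L
    for (it in seq_len(niter)) {
      prop <- par + rnorm(npar, 0, psd)
      llp <- model$logLik(prop, data)
      lpp <- model$logPrior(prop)
      if (is.finite(llp + lpp) &&
          log(runif(1)) < (lpp + beta * llp) - (lp + beta * ll)) {
        par <- prop; ll <- llp; lp <- lpp
        acc <- acc + 1L
      }
      win <- win + 1L
      if (it <= burnin && win == 50L) {
        rate <- acc / win
        psd <- psd * exp(rate - 0.3)
        acc <- 0L; win <- 0L
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        keep[kept] <- ll
      }
    }
    samples[[k]] <- keep
    ess[k] <- essOf(keep)
  }
  warns <- character()
  if (any(ess < 50))
    warns <- sprintf("low effective sample size (<50) at %d rung(s)",
                     sum(ess < 50))
  list(trace = powerPosteriorTrace(betas, samples), ess = ess, warnings = warns)
}

#' Heterochronous-vs-isochronous comparison on a desk-scale model
#'
#' Runs power-posterior sampling for the same model on the dated
#' (heterochronous) and date-constrained (isochronous) datasets, estimates
#' both log marginal likelihoods by path sampling and stepping stone, and
#' returns the Bayes-factor comparison (log-bf orientation: positive favors
#' heterochronous).
#'
#' @param model model spec.
#' @param dataHet,dataIso the two datasets.
#' @param ladderSize rungs in the power ladder.
#' @param samplesPerRung retained samples per rung.
#' @param seed RNG seed.
#' @param estimator \code{"PS"} or \code{"SS"} used for the headline BF.
#' @return list(comparison = BetsComparison, het = list(PS=,SS=), iso = ...,
#'   traces = list(het=, iso=), envelope = results envelope).
#' @export
runBetsToy <- function(model, dataHet, dataIso, ladderSize = 20L,
                       samplesPerRung = 500L, seed = 1L,
                       estimator = c("PS", "SS")) {
  estimator <- match.arg(estimator)
  betas <- betaLadder(ladderSize)
  het <- powerPosteriorSample(model, dataHet, betas, samplesPerRung,
                              seed = seed)
  iso <- powerPosteriorSample(model, dataIso, betas, samplesPerRung,
                              seed = seed + 1L)
  psHet <- pathSamplingLogML(het$trace); ssHet <- steppingStoneLogML(het$trace)
  psIso <- pathSamplingLogML(iso$trace); ssIso <- steppingStoneLogML(iso$trace)
  mlHet <- if (estimator == "PS") psHet else ssHet
  mlIso <- if (estimator == "PS") psIso else ssIso
  cmp <- betsCompare(logML(mlHet), logML(mlIso), convention = "log-bf")
  env <- resultsEnvelope("bets-toy",
    params = list(ladderSize = ladderSize, samplesPerRung = samplesPerRung,
                  estimator = estimator),
    results = list(bayesFactor = cmp@bayesFactor, favored = cmp@favored),
    seed = seed, warnings = c(het$warnings, iso$warnings))
  list(comparison = cmp,
       het = list(PS = psHet, SS = ssHet), iso = list(PS = psIso, SS = ssIso),
       traces = list(het = het$trace, iso = iso$trace), envelope = env)
}

#' Exact power-posterior trace for the conjugate normal model
#'
#' Samples each rung's tempered posterior exactly (no MCMC); used to study
#' estimator behavior against the closed-form marginal likelihood.
#'
#' @param model a \code{conjugateNormalModel}.
#' @param data numeric observations.
#' @param betas power ladder.
#' @param samplesPerRung samples per rung.
#' @param seed RNG seed.
#' @return a \code{PowerPosteriorTrace}.
#' @export
conjugateNormalTrace <- function(model, data, betas = betaLadder(50L),
                                 samplesPerRung = 1000L, seed = 1L) {
  set.seed(seed)
  samples <- lapply(betas, function(b) {
    mu <- model$exactRungSampler(data, b, samplesPerRung)
    vapply(mu, function(m) model$logLik(m, data), 1.0)
  })
  powerPosteriorTrace(betas, samples)
}
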