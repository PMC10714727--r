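## Branch-site codon models of episodic positive selection (four-class
## mixture; alternative with free foreground omega2 >= 1 vs null with
## omega2 = 1), the likelihood-ratio test, and the epoch-level
## adaptive-divergence statistic sum(omega2)/kappa.

## 61x61 structural masks of the GY94-style model, built once
codonEnv <- new.env(parent = emptyenv())

codonStructure <- function() {
  if (!is.null(codonEnv$struct)) return(codonEnv$struct)
  cods <- senseCodons()
  aas <- codonAminoAcids()
  n <- length(cods)
  spl <- do.call(rbind, strsplit(cods, ""))
  ts <- tv <- nonsyn <- matrix(0, n, n, dimnames = list(cods, cods))
  ispur <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (i in seq_len(n)) {
    diffs <- spl[rep(i, n), , drop = FALSE] != spl
    ndiff <- rowSums(diffs)
    one <- which(ndiff == 1L)
    for (j in one) {
      pos <- which(diffs[j, ])
      if (ispur(spl[i, pos], spl[j, pos])) ts[i, j] <- 1 else tv[i, j] <- 1
      if (aas[i] != aas[j]) nonsyn[i, j] <- 1
    }
  }
  codonEnv$struct <- list(codons = cods, aas = aas, ts = ts, tv = tv,
                          nonsyn = nonsyn)
  codonEnv$struct
}

#' Codon equilibrium frequencies from an alignment
#'
#' @param aln codon \code{MsaAlignment}.
#' @param method \code{"F3x4"} (position-specific nucleotide frequencies),
#'   \code{"F1x4"} (pooled) or \code{"equal"}.
#' @return numeric vector over the 61 sense codons (sums to 1).
#' @export
codonFrequencies <- function(aln, method = c("F3x4", "F1x4", "equal")) {
  method <- match.arg(method)
  cods <- senseCodons()
  if (method == "equal") return(setNames(rep(1 / 61, 61), cods))
  m <- gsub("U", "T", alignmentMatrix(aln))
  pos <- (seq_len(ncol(m)) - 1L) %% 3L + 1L
  spl <- do.call(rbind, strsplit(cods, ""))
  if (method == "F1x4") {
    cnt <- table(factor(m[m %in% NT], levels = NT))
    f <- (as.numeric(cnt) + 1) / (sum(cnt) + 4)
    pi <- f[match(spl[, 1], NT)] * f[match(spl[, 2], NT)] * f[match(spl[, 3], NT)]
  } else {
    f <- sapply(1:3, function(p) {
      v <- m[, pos == p]
      cnt <- table(factor(v[v %in% NT], levels = NT))
      (as.numeric(cnt) + 1) / (sum(cnt) + 4)
    })
    pi <- f[match(spl[, 1], NT), 1] * f[match(spl[, 2], NT), 2] *
      f[match(spl[, 3], NT), 3]
  }
  setNames(pi / sum(pi), cods)
}

#' GY94-style codon rate matrix
#'
#' Single-nucleotide codon exchanges with transition/transversion ratio
#' \code{kappa} and nonsynonymous/synonymous ratio \code{omega}; target-codon
#' frequencies \code{pi}. The matrix is scaled so that one unit of branch
#' length equals one expected substitution per codon for a neutral
#' (omega = 1) site with the same kappa; site classes therefore keep their
#' relative speeds.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi codon frequencies over the 61 sense codons.
#' @return 61 x 61 rate matrix.
#' @export
codonRateMatrix <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  st <- codonStructure()
  pi <- pi / sum(pi)
  mult <- kappa * st$ts + st$tv
  mult1 <- mult                                   # omega = 1 reference
  mult <- mult * (1 + (omega - 1) * st$nonsyn)
  Q <- sweep(mult, 2, pi, "*")
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  Q1 <- sweep(mult1, 2, pi, "*")
  diag(Q1) <- 0; diag(Q1) <- -rowSums(Q1)
  normC <- sum(pi * -diag(Q1))
  out <- Q / normC
  dimnames(out) <- list(st$codons, st$codons)
  out
}

## codon states (0-based index into senseCodons(); -1 = unusable) per
## sequence x codon column
codonStates <- function(aln) {
  cm <- gsub("U", "T", codonMatrix(aln))
  idx <- match(cm, senseCodons())
  matrix(ifelse(is.na(idx), -1L, idx - 1L), nrow(cm),
         dimnames = dimnames(cm))
}

## model-A class weights from (p0, p1)
modelAWeights <- function(p0, p1) {
  p2 <- 1 - p0 - p1
  s <- p0 + p1
  c(p0, p1, p2 * p0 / s, p2 * p1 / s)
}

## mixture log-likelihood for given parameters; statesPat: ntip x npat,
## w: pattern weights
branchSiteLogLik <- function(statesPat, w, tr, blenSubst, foregroundEdge,
                             p0, p1, omega0, omega2, kappa, pi) {
  st <- codonStructure()
  po <- ape::postorder(tr)
  edge <- tr$edge[po, , drop = FALSE]
  blen <- blenSubst[po]
  fg <- as.integer(seq_len(nrow(tr$edge)) %in% foregroundEdge)[po]
  M <- .cpp_branchsite_loglik(statesPat, edge, blen, fg,
                              omegaBg = c(omega0, 1, omega0, 1),
                              omegaFg = c(omega0, 1, omega2, omega2),
                              kappa = kappa, pi = pi,
                              ts = st$ts, tv = st$tv, nonsyn = st$nonsyn)
  lw <- log(modelAWeights(p0, p1))
  mx <- apply(M, 2, max)
  site <- mx + log(colSums(exp(M - rep(mx, each = 4L)) * exp(lw)))
  sum(w * site)
}

#' Fit the branch-site codon model
#'
#' Four site classes: 0 (omega0 everywhere), 1 (neutral everywhere), 2a
#' (omega0 background / omega2 foreground) and 2b (neutral background /
#' omega2 foreground), with weights derived from (p0, p1) in the standard
#' model-A construction. Likelihood is computed by pruning over the 61 sense
#' codons with a GY94-style rate matrix (kappa, F3x4 frequencies by default).
#' Branch lengths are taken from the timed tree up to one free rate scaling.
#' Parameters are optimized on an unconstrained scale (softmax proportions,
#' logit omega0, log rates) with multiple restarts; \code{fixOmega2 = TRUE}
#' pins omega2 = 1 (the null model).
#'
#' The returned object contains both fits and the chi-square(1) LRT.
#'
#' @param aln codon \code{MsaAlignment}; columns containing gaps or
#'   ambiguity are excluded.
#' @param x the \code{TimedTree} (branch lengths in years).
#' @param foreground integer vector of foreground edge indices (rows of
#'   \code{treeOf(x)$edge}).
#' @param freqMethod codon frequency model (\code{"F3x4"}, \code{"F1x4"},
#'   \code{"equal"}).
#' @param nRestarts random restarts per model (first start is deterministic).
#' @param alpha significance level for the \code{significant} flag.
#' @param lrtReference \code{"chisq1"} (plain chi-square, df 1) or
#'   \code{"mixture"} (50:50 mixture of chi-square 0 and 1).
#' @return a \code{BranchSiteFit}.
#' @export
fitBranchSiteModel <- function(aln, x, foreground,
                               freqMethod = c("F3x4", "F1x4", "equal"),
                               nRestarts = 2L, alpha = 0.05,
                               lrtReference = c("chisq1", "mixture")) {
  freqMethod <- match.arg(freqMethod)
  lrtReference <- match.arg(lrtReference)
  stopifnot(is(aln, "MsaAlignment"), alphabetOf(aln) == "codon",
            is(x, "TimedTree"))
  tr <- treeOf(x)
  nedge <- nrow(tr$edge)
  foreground <- as.integer(foreground)
  if (length(foreground) == 0L) stop("foreground branch set must be non-empty")
  if (any(foreground < 1L | foreground > nedge))
    stop("foreground contains invalid edge indices")
  if (length(foreground) >= nedge)
    stop("foreground must be a proper subset of the branches")

  states <- codonStates(aln)
  miss <- setdiff(tr$tip.label, rownames(states))
  if (length(miss)) stop("alignment missing tips: ", paste(miss, collapse = ", "))
  states <- states[tr$tip.label, , drop = FALSE]
  usable <- colSums(states < 0L) == 0L   # drop columns with gap/ambiguity
  if (!any(usable)) stop("no usable codon columns")
  states <- states[, usable, drop = FALSE]

  key <- apply(states, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[upat])))
  statesPat <- states[, upat, drop = FALSE]

  pi <- unname(codonFrequencies(aln, freqMethod))
  blenYears <- tr$edge.length
  treeSpan <- sum(blenYears)

  obj <- function(par, fixOmega2) {
    ea <- exp(par[1]); eb <- exp(par[2])
    den <- 1 + ea + eb
    p0 <- ea / den; p1 <- eb / den
    omega0 <- 1 / (1 + exp(-par[3]))
    kappa <- exp(par[4])
    scale <- exp(par[5])
    omega2 <- if (fixOmega2) 1 else 1 + exp(par[6])
    ll <- branchSiteLogLik(statesPat, w, tr, blenYears * scale, foreground,
                           p0, p1, omega0, omega2, kappa, pi)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  scale0 <- log(max(0.5 / max(treeSpan, 1e-9), 1e-8))
  base <- c(1, 0, qlogis(0.2), log(2), scale0)
  fitOne <- function(fixOmega2, inits) {
    best <- NULL
    for (init in inits) {
      f <- tryCatch(
        nlminb(init, obj, fixOmega2 = fixOmega2,
               control = list(iter.max = 200, eval.max = 500, rel.tol = 1e-10)),
        error = function(e) NULL)
      if (is.null(f)) next
      if (is.null(best) || f$objective < best$objective) best <- f
    }
    if (is.null(best))
      stop("branch-site optimizer failed on all restarts")
    best
  }

  jitter_inits <- function(base, n) {
    out <- list(base)
    if (n > 1L) {
      extra <- withLocalSeed(7L, lapply(seq_len(n - 1L), function(i)
        base + rnorm(length(base), 0, 0.7)))
      out <- c(out, extra)
    }
    out
  }

  ## null model (omega2 pinned at 1)
  nullFit <- fitOne(TRUE, jitter_inits(base, nRestarts))
  pnull <- nullFit$par
  ## alternative warm-started from the null: screen omega2 = 1 + exp(u) on a
  ## coarse grid at the null solution and optimize from the two best starts
  ## (keeps the fits nested and avoids the local optimum at omega2 ~ 1),
  ## plus jittered restarts
  uGrid <- log(c(1e-6, 0.5, 2, 6, 16))
  ou <- vapply(uGrid, function(u) obj(c(pnull, u), FALSE), 1.0)
  nStarts <- if (nRestarts >= 2L) 2L else 1L
  best2 <- uGrid[order(ou)[seq_len(nStarts)]]
  altInits <- c(lapply(best2, function(u) c(pnull, u)),
                lapply(jitter_inits(base, nRestarts)[-1],
                       function(p) c(p, log(0.5))))
  altFit <- fitOne(FALSE, altInits)

  lnLNull <- -nullFit$objective
  lnLAlt <- -altFit$objective
  if (lnLAlt < lnLNull - 1e-6) {
    ## nested models: alt can never be worse; fall back to the null solution
    altFit$par <- c(pnull, log(1e-9))
    altFit$objective <- nullFit$objective
    lnLAlt <- lnLNull
  }

  unpack <- function(par, fixOmega2) {
    ea <- exp(par[1]); eb <- exp(par[2]); den <- 1 + ea + eb
    list(p0 = ea / den, p1 = eb / den,
         omega0 = 1 / (1 + exp(-par[3])),
         omega2 = if (fixOmega2) 1 else 1 + exp(par[6]),
         kappa = exp(par[4]), scale = exp(par[5]))
  }
  pAlt <- unpack(altFit$par, FALSE)
  pNull <- unpack(nullFit$par, TRUE)

  test <- lrt(lnLAlt, lnLNull, df = 1)
  pval <- if (lrtReference == "mixture") {
    if (test$statistic <= 0) 1 else
      0.5 * pchisq(test$statistic, 1, lower.tail = FALSE)
  } else test$pValue

  new("BranchSiteFit", foreground = foreground, lnLAlt = lnLAlt,
      lnLNull = lnLNull, params = pAlt, nullParams = pNull,
      lrtStat = test$statistic, df = 1, pValue = pval,
      significant = (pval < alpha) && pAlt$omega2 > 1)
}

#' Likelihood-ratio test
#'
#' @param lnLAlt,lnLNull maximized log-likelihoods of nested models.
#' @param df degrees of freedom (difference in free parameters).
#' @param tol tolerance for a (numerically) negative likelihood gain.
#' @return list(statistic, pValue); the statistic is 2 * (lnLAlt - lnLNull)
#'   clipped at zero, compared to the chi-square upper tail.
#' @export
lrt <- function(lnLAlt, lnLNull, df = 1, tol = 1e-6) {
  delta <- lnLAlt - lnLNull
  if (delta < -tol)
    stop("lnL of the alternative model is below the null (",
         format(delta, digits = 6), "); optimizer failure upstream")
  stat <- max(0, 2 * delta)
  list(statistic = stat, pValue = pchisq(stat, df, lower.tail = FALSE))
}

#' Adaptive divergence per 50-year window
#'
#' For each window (stepping back from the latest tip) the statistic is the
#' sum of the estimated foreground omega2 over branches that are statistically
#' supported (p below \code{alpha} and omega2 > 1) and whose temporal midpoint
#' falls in the window, divided by the kappa of the window's epoch. Windows
#' with no supported branch score 0.
#'
#' @param fits list of \code{BranchSiteFit} named by edge index, or a
#'   data.frame with columns \code{edge}, \code{omega2}, \code{pValue}.
#' @param x the \code{TimedTree}.
#' @param partition the \code{EpochPartition} used for kappa.
#' @param kappas data.frame from \code{estimateEpochKappa} (columns
#'   \code{epoch}, \code{kappa}) or a numeric vector indexed by epoch.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame per window: \code{windowStart}, \code{windowEnd}
#'   (calendar years), \code{epoch}, \code{sumOmega2}, \code{kappa}, \code{AD}.
#' @export
adaptiveDivergence <- function(fits, x, partition, kappas, alpha = 0.05) {
  stopifnot(is(x, "TimedTree"), is(partition, "EpochPartition"))
  if (is.data.frame(fits)) {
    tab <- fits
    if (!all(c("edge", "omega2", "pValue") %in% names(tab)))
      stop("fits data.frame needs columns edge, omega2, pValue")
  } else {
    tab <- data.frame(
      edge = as.integer(names(fits)),
      omega2 = vapply(fits, function(f) f@params$omega2, 1.0),
      pValue = vapply(fits, function(f) f@pValue, 1.0))
  }
  if (is.data.frame(kappas)) {
    kv <- rep(NA_real_, max(kappas$epoch))
    kv[kappas$epoch] <- kappas$kappa
  } else kv <- as.numeric(kappas)

  tr <- treeOf(x)
  h <- nodeHeights(x)
  wYears <- partition@windowYears
  nE <- partition@nEpochs
  rootH <- max(h)
  nWin <- max(1L, ceiling(rootH / wYears - 1e-12))
  latest <- latestTipDate(x)

  epochOfHeight <- function(hh)
    as.integer(nE - pmin(floor(hh / wYears), nE - 1L))

  sel <- tab$pValue < alpha & tab$omega2 > 1
  midH <- (h[tr$edge[tab$edge, 1L]] + h[tr$edge[tab$edge, 2L]]) / 2
  winOf <- pmin(pmax(1L, as.integer(floor(midH / wYears)) + 1L), nWin)

  out <- data.frame(
    windowStart = latest - wYears * seq_len(nWin),
    windowEnd = latest - wYears * (seq_len(nWin) - 1L),
    epoch = epochOfHeight(wYears * (seq_len(nWin) - 0.5)),
    sumOmega2 = 0, kappa = NA_real_, AD = 0)
  out$kappa <- kv[out$epoch]
  for (i in which(sel)) {
    wi <- winOf[i]
    out$sumOmega2[wi] <- out$sumOmega2[wi] + tab$omega2[i]
  }
  need <- out$sumOmega2 > 0
  if (any(need & (is.na(out$kappa) | out$kappa <= 0)))
    stop("kappa missing for epoch(s) ",
         paste(unique(out$epoch[need & is.na(out$kappa)]), collapse = ", "),
         " required by supported branches")
  out$AD[need] <- out$sumOmega2[need] / out$kappa[need]
  out
}
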