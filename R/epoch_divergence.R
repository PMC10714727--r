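## Epoch partitioning of timed trees and per-epoch transition/transversion
## (kappa) estimation under an HKY model fitted by maximum likelihood with the
## pruning algorithm.

#' Partition a timed tree into fixed-width epochs
#'
#' Epochs are windows of \code{windowYears} anchored at the latest tip date
#' and stepped back in time; the oldest epoch absorbs everything beyond the
#' last boundary. Epoch 1 is the oldest, epoch \code{nEpochs} the most recent.
#' Each branch is assigned the epoch containing its temporal midpoint, and the
#' exact fraction of its span inside every epoch is also reported for
#' sensitivity analyses.
#'
#' @param x a \code{TimedTree}.
#' @param nEpochs number of epochs (default 3).
#' @param windowYears epoch width in years (default 50).
#' @return an \code{EpochPartition}; rows of \code{fractions} and names of
#'   \code{epochOf} are edge indices of \code{treeOf(x)}.
#' @export
assignEpochs <- function(x, nEpochs = 3L, windowYears = 50) {
  stopifnot(is(x, "TimedTree"), nEpochs >= 1L, windowYears > 0)
  tr <- treeOf(x)
  h <- nodeHeights(x)
  nE <- as.integer(nEpochs)
  ne <- nrow(tr$edge)
  ## height intervals: epoch e (1 = oldest) covers heights
  ## [w*(nE-e), w*(nE-e+1)) except epoch 1 extends to +Inf
  lower <- windowYears * (nE - seq_len(nE))
  upper <- windowYears * (nE - seq_len(nE) + 1L)
  upper[1L] <- Inf

  epochOfHeight <- function(hh) {
    bin <- pmin(floor(hh / windowYears), nE - 1L)
    as.integer(nE - bin)
  }

  hc <- h[tr$edge[, 2L]]
  hp <- h[tr$edge[, 1L]]
  mid <- (hc + hp) / 2
  epochOf <- epochOfHeight(mid)
  names(epochOf) <- as.character(seq_len(ne))

  frac <- matrix(0, ne, nE,
                 dimnames = list(seq_len(ne), paste0("Q", seq_len(nE))))
  span <- hp - hc
  for (e in seq_len(nE)) {
    ov <- pmax(0, pmin(hp, upper[e]) - pmax(hc, lower[e]))
    frac[, e] <- ifelse(span > 0, ov / span, as.numeric(epochOf == e))
  }

  latest <- latestTipDate(x)
  boundaries <- latest - windowYears * ((nE - 1L):1L)
  if (nE == 1L) boundaries <- numeric()
  new("EpochPartition", boundaries = boundaries, epochOf = epochOf,
      fractions = frac, nEpochs = nE, windowYears = windowYears,
      latestDate = latest)
}

## ---------------------------------------------------------------------------
## HKY machinery (4-state; used by the per-epoch kappa fit and the DNA
## generator)
## ---------------------------------------------------------------------------

NT <- c("A", "C", "G", "T")

## HKY rate matrix (A,C,G,T order), scaled to one expected substitution per
## unit branch length
hkyMatrix <- function(kappa, freqs) {
  stopifnot(length(freqs) == 4L, all(freqs > 0))
  freqs <- freqs / sum(freqs)
  ts <- matrix(FALSE, 4, 4, dimnames = list(NT, NT))
  ts["A", "G"] <- ts["G", "A"] <- ts["C", "T"] <- ts["T", "C"] <- TRUE
  Q <- matrix(freqs, 4, 4, byrow = TRUE)
  Q[ts] <- Q[ts] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(NT, NT)
  Q / sum(freqs * -diag(Q))
}

## P(t) for a reversible rate matrix via symmetric eigendecomposition
revPmat <- function(Q, freqs, t) {
  freqs <- freqs / sum(freqs)
  s <- sqrt(freqs)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- diag(1 / s) %*% e$vectors %*% (exp(e$values * t) *
                                      (t(e$vectors) %*% diag(s)))
  P[P < 0] <- 0
  P
}

dnaStateIndex <- function(ch) {
  i <- match(ch, NT)
  i[is.na(i)] <- 0L
  i - 1L  # ambiguity/gap -> -1 (missing)
}

## HKY log-likelihood by pruning with one kappa per edge group.
## blen: substitution-unit branch lengths; kappaOf: kappa index per edge;
## w: per-pattern weights.
hkyLogLik <- function(tipStates, tr, blen, kappas, kappaOf, freqs,
                      w = rep(1, ncol(tipStates))) {
  ntip <- ape::Ntip(tr)
  po <- ape::postorder(tr)
  edge <- tr$edge
  npat <- ncol(tipStates)
  freqs <- freqs / sum(freqs)
  s <- sqrt(freqs)
  Plist <- vector("list", nrow(edge))
  for (k in seq_along(kappas)) {
    idx <- which(kappaOf == k)
    if (!length(idx)) next
    Q <- hkyMatrix(kappas[k], freqs)
    B <- diag(s) %*% Q %*% diag(1 / s)
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    L <- diag(1 / s) %*% e$vectors
    R <- t(e$vectors) %*% diag(s)
    for (ed in idx) {
      P <- L %*% (exp(e$values * blen[ed]) * R)
      P[P < 0] <- 0
      Plist[[ed]] <- P
    }
  }
  partial <- vector("list", ntip + tr$Nnode)
  logscale <- numeric(npat)
  for (ed in po) {
    par <- edge[ed, 1L]; ch <- edge[ed, 2L]
    P <- Plist[[ed]]
    if (ch <= ntip) {
      contrib <- matrix(1, 4, npat)
      st <- tipStates[ch, ]
      ok <- st >= 0L
      if (any(ok)) contrib[, ok] <- P[, st[ok] + 1L]
    } else {
      contrib <- P %*% partial[[ch]]
    }
    partial[[par]] <- if (is.null(partial[[par]])) contrib
                      else partial[[par]] * contrib
    mx <- apply(partial[[par]], 2, max)
    if (any(mx < 1e-120)) {
      mx[mx <= 0] <- 1
      partial[[par]] <- sweep(partial[[par]], 2, mx, "/")
      logscale <- logscale + log(mx)
    }
  }
  root <- edge[po[length(po)], 1L]
  lik <- colSums(freqs * partial[[root]])
  sum(w * (log(lik) + logscale))
}

#' Per-epoch transition/transversion ratio by maximum likelihood
#'
#' Fits an HKY model with empirical base frequencies in which kappa (the
#' transition/transversion rate ratio) takes one free value per epoch;
#' branches are mapped to epochs by their temporal midpoint. A single
#' substitution-rate scaling of the (year-unit) branch lengths is estimated
#' jointly. Standard errors come from the observed-information diagonal on
#' the log scale (delta method back to kappa).
#'
#' Alignment columns are compressed to site patterns; ambiguity codes and
#' gaps enter the likelihood as missing data.
#'
#' @param aln a DNA \code{MsaAlignment} covering all tips of the tree.
#' @param x the \code{TimedTree}.
#' @param partition an \code{EpochPartition} of \code{x}.
#' @return data.frame with one row per epoch: \code{epoch}, \code{kappa},
#'   \code{se}, \code{nBranches}; attributes \code{logLik} and \code{rate}
#'   (substitutions/site/year).
#' @export
estimateEpochKappa <- function(aln, x, partition = assignEpochs(x)) {
  stopifnot(is(aln, "MsaAlignment"), alphabetOf(aln) %in% c("dna", "codon"),
            is(x, "TimedTree"))
  tr <- treeOf(x)
  m <- alignmentMatrix(aln)
  miss <- setdiff(tr$tip.label, rownames(m))
  if (length(miss)) stop("alignment missing tips: ", paste(miss, collapse = ", "))
  m <- m[tr$tip.label, , drop = FALSE]
  states <- matrix(dnaStateIndex(gsub("U", "T", m)), nrow(m))

  key <- apply(states, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[upat])))
  states <- states[, upat, drop = FALSE]

  cnt <- table(factor(m[m %in% NT], levels = NT))
  freqs <- (as.numeric(cnt) + 1) / (sum(cnt) + 4)  # light smoothing

  nE <- partition@nEpochs
  kappaOf <- partition@epochOf
  present <- sort(unique(kappaOf))
  if (length(present) < nE)
    warning("epoch(s) without branches: ",
            paste(setdiff(seq_len(nE), present), collapse = ", "),
            "; kappa reported as NA")
  kmap <- match(kappaOf, present)

  blenYears <- tr$edge.length
  nll <- function(par) {
    kappas <- exp(par[seq_along(present)])
    rate <- exp(par[length(par)])
    ll <- hkyLogLik(states, tr, blenYears * rate, kappas, kmap, freqs, w)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  rh <- max(nodeHeights(x))
  init <- c(rep(log(2), length(present)), log(0.1 / max(rh, 1)))
  fit <- nlminb(init, nll, control = list(iter.max = 300, eval.max = 600))
  H <- tryCatch(optimHess(fit$par, nll), error = function(e) NULL)
  se_log <- rep(NA_real_, length(present))
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)[seq_along(present)]
      se_log <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }
  kappas <- exp(fit$par[seq_along(present)])
  out <- data.frame(epoch = seq_len(nE), kappa = NA_real_, se = NA_real_,
                    nBranches = as.vector(table(factor(kappaOf, seq_len(nE)))))
  out$kappa[present] <- kappas
  out$se[present] <- kappas * se_log
  attr(out, "logLik") <- -fit$objective
  attr(out, "rate") <- exp(fit$par[length(fit$par)])
  out
}
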