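## Type I and type II functional divergence between two sequence clusters,
## with site-specific posterior probabilities (Qk).

#' Define a cluster pair on a tree
#'
#' @param x rooted tree (\code{TimedTree} or \code{phylo}).
#' @param cluster1,cluster2 tip label vectors; each must be monophyletic in
#'   the tree and contain at least 4 taxa.
#' @return list with elements \code{cluster1}, \code{cluster2},
#'   \code{subtree1}, \code{subtree2}.
#' @export
clusterPair <- function(x, cluster1, cluster2) {
  tr <- if (is(x, "TimedTree")) treeOf(x) else x
  cluster1 <- normalizeStrainId(cluster1)
  cluster2 <- normalizeStrainId(cluster2)
  if (length(intersect(cluster1, cluster2)))
    stop("clusters overlap: ", paste(intersect(cluster1, cluster2), collapse = ", "))
  if (length(cluster1) < 4L || length(cluster2) < 4L)
    stop("each cluster needs at least 4 taxa")
  for (cl in list(cluster1, cluster2)) {
    miss <- setdiff(cl, tr$tip.label)
    if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
    if (!ape::is.monophyletic(tr, cl)) {
      mrca <- ape::getMRCA(tr, cl)
      below <- tr$tip.label[unlist(phangornFreeDescendants(tr, mrca))]
      extra <- setdiff(below, cl)
      stop("cluster not monophyletic; clade also contains: ",
           paste(head(extra, 10), collapse = ", "))
    }
  }
  list(cluster1 = cluster1, cluster2 = cluster2,
       subtree1 = ape::keep.tip(tr, cluster1),
       subtree2 = ape::keep.tip(tr, cluster2))
}

## tips below a node (ape utilities without extra deps)
phangornFreeDescendants <- function(tr, node) {
  ntip <- ape::Ntip(tr)
  if (node <= ntip) return(list(node))
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    ch <- tr$edge[tr$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  list(out)
}

## Fitch parsimony count for one column on one tree; states: named character
## (by tip label); gaps/unknown count as missing (wildcard)
fitchCount <- function(tr, states) {
  ntip <- ape::Ntip(tr)
  lv <- sort(unique(states[states %in% AA_LETTERS]))
  if (length(lv) <= 1L) return(0L)
  bit <- setNames(bitwShiftL(1L, seq_along(lv) - 1L), lv)
  full <- sum(bit)
  sets <- integer(ntip + tr$Nnode)
  st <- states[tr$tip.label]
  sets[seq_len(ntip)] <- ifelse(st %in% lv, bit[st], full)
  changes <- 0L
  po <- ape::postorder(tr)
  edge <- tr$edge
  done <- logical(ntip + tr$Nnode)
  kids <- split(edge[, 2], edge[, 1])
  for (nd in unique(edge[po, 1])) {
    s <- full
    first <- TRUE
    acc <- 0L
    for (ch in kids[[as.character(nd)]]) {
      cs <- sets[ch]
      inter <- bitwAnd(acc, cs)
      if (first) { acc <- cs; first <- FALSE }
      else if (inter != 0L) acc <- inter
      else { acc <- bitwOr(acc, cs); changes <- changes + 1L }
    }
    sets[nd] <- acc
  }
  changes
}

#' Minimum substitution counts per column within each cluster
#'
#' Fitch parsimony minimum changes for every alignment column, computed
#' separately on each cluster's subtree; gaps are missing data (no change
#' contribution). Columns that are entirely gap in both clusters are dropped.
#'
#' @param aln protein \code{MsaAlignment}.
#' @param x rooted tree covering both clusters.
#' @param clusters a \code{clusterPair}.
#' @return list: \code{X1}, \code{X2} integer vectors, \code{T1}, \code{T2}
#'   subtree total branch lengths, \code{columns} retained column indices,
#'   \code{n1}, \code{n2} cluster sizes.
#' @export
countSiteChanges <- function(aln, x, clusters) {
  stopifnot(is(aln, "MsaAlignment"), alphabetOf(aln) == "protein")
  m <- alignmentMatrix(aln)
  for (cl in list(clusters$cluster1, clusters$cluster2)) {
    miss <- setdiff(cl, rownames(m))
    if (length(miss)) stop("alignment missing: ", paste(miss, collapse = ", "))
  }
  t1 <- clusters$subtree1; t2 <- clusters$subtree2
  m1 <- m[t1$tip.label, , drop = FALSE]
  m2 <- m[t2$tip.label, , drop = FALSE]
  keep <- which(apply(m1, 2, function(cc) any(cc %in% AA_LETTERS)) |
                  apply(m2, 2, function(cc) any(cc %in% AA_LETTERS)))
  X1 <- vapply(keep, function(j) fitchCount(t1, setNames(m1[, j], rownames(m1))),
               0L)
  X2 <- vapply(keep, function(j) fitchCount(t2, setNames(m2[, j], rownames(m2))),
               0L)
  list(X1 = X1, X2 = X2,
       T1 = sum(t1$edge.length), T2 = sum(t2$edge.length),
       columns = keep, n1 = ape::Ntip(t1), n2 = ape::Ntip(t2),
       subtree1 = t1, subtree2 = t2)
}

## Parsimony counting channel of a subtree: minimum-change counts
## systematically undershoot the true substitution count (per-branch
## censoring and ancestral-state reassignment), which deflates the apparent
## rate variance and biases theta downward. The channel is calibrated once by
## simulating a 20-state process on the subtree across a grid of expected
## substitution loads and recording the mean Fitch count; the returned
## function maps an observed count back to the expected-substitution scale.
parsimonyChannel <- function(subtree,
                             sGrid = exp(seq(log(0.05), log(80),
                                             length.out = 18L)),
                             R = 36L, seed = 99L) {
  Ttot <- sum(subtree$edge.length)
  ntip <- ape::Ntip(subtree)
  po <- ape::postorder(subtree)
  E <- subtree$edge
  nn <- ntip + subtree$Nnode
  rootN <- E[po[length(po)], 1L]
  pre <- rev(po)
  mu <- withLocalSeed(seed, vapply(sGrid, function(s) {
    states <- matrix(0L, nn, R)
    states[rootN, ] <- sample.int(20L, R, TRUE)
    for (ed in pre) {
      d <- subtree$edge.length[ed] / Ttot * s
      st <- states[E[ed, 1L], ]
      ch <- runif(R) > (1 / 20 + 19 / 20 * exp(-d * 20 / 19))
      if (any(ch))
        st[ch] <- ((st[ch] - 1L + sample.int(19L, sum(ch), TRUE)) %% 20L) + 1L
      states[E[ed, 2L], ] <- st
    }
    m <- matrix(AA_LETTERS[states[seq_len(ntip), ]], ntip,
                dimnames = list(subtree$tip.label, NULL))
    mean(vapply(seq_len(R), function(j)
      fitchCount(subtree, setNames(m[, j], rownames(m))), 0L))
  }, 1.0))
  mu <- cummax(mu)
  stats::approxfun(c(0, mu), c(0, sGrid), rule = 2)
}

## log density of the negative-binomial marginal of Poisson(lambda*T) with
## lambda ~ Gamma(shape a, mean m) (rate b = a/m)
lnbMarginal <- function(x, Texp, a, m) {
  b <- a / m
  lgamma(a + x) - lgamma(a) - lgamma(x + 1) +
    a * (log(b) - log(b + Texp)) + x * (log(Texp) - log(b + Texp))
}

## shared-rate bivariate marginal: lambda ~ Gamma(a, mean m) common to both
lnbShared <- function(x1, x2, T1, T2, a, m) {
  b <- a / m
  lgamma(a + x1 + x2) - lgamma(a) - lgamma(x1 + 1) - lgamma(x2 + 1) +
    a * (log(b) - log(b + T1 + T2)) +
    x1 * log(T1) + x2 * log(T2) - (x1 + x2) * log(b + T1 + T2)
}

#' Type I functional divergence (rate-shift model)
#'
#' Two-state mixture over columns: with probability 1 - theta the column's
#' substitution rate is shared between the clusters (one gamma-distributed
#' rate driving Poisson counts in both subtrees); with probability theta the
#' two clusters draw independent rates from the same gamma. A per-cluster
#' mean-rate multiplier absorbs systematic rate differences between the
#' clusters in both states, so the states differ only in whether the rates
#' are correlated -- the actual rate-shift signal. All parameters are
#' estimated by maximum likelihood through the marginal negative-binomial
#' forms. Qk is the posterior probability of the independent-rate (divergent)
#' state; theta = 0 is tested with a boundary-aware LRT (50:50 mixture of
#' chi-square 0 and 1).
#'
#' @param counts output of \code{countSiteChanges}.
#' @param qkCutoff flagging cutoff for site posteriors (default 0.98).
#' @param channelCorrection \code{"calibrated"} (default; requires the
#'   subtrees in \code{counts}) maps parsimony counts back to the
#'   expected-substitution scale through a simulated counting-channel curve
#'   before the Poisson-gamma likelihood is applied; \code{"none"} uses the
#'   raw counts.
#' @return list(theta = \code{ThetaEstimate}, posterior = \code{SitePosterior}).
#' @export
estimateThetaI <- function(counts, qkCutoff = 0.98,
                           channelCorrection = c("calibrated", "none")) {
  channelCorrection <- match.arg(channelCorrection)
  X1 <- counts$X1; X2 <- counts$X2
  T1 <- counts$T1; T2 <- counts$T2
  if (channelCorrection == "calibrated" &&
      !is.null(counts$subtree1) && !is.null(counts$subtree2)) {
    X1 <- parsimonyChannel(counts$subtree1)(X1)
    X2 <- parsimonyChannel(counts$subtree2)(X2)
  }
  if (all(X1 == 0) && all(X2 == 0))
    stop("degenerate input: no substitutions in either cluster")
  n <- length(X1)
  if (n < 50) warning("fewer than 50 columns; theta estimate may be unstable")

  ## par: alpha (shape), m (mean rate, cluster 1), r2 (cluster-2 multiplier)
  loglik_parts <- function(th, a, m, r2) {
    lsh <- lnbShared(X1, X2, T1, r2 * T2, a, m)
    lin <- lnbMarginal(X1, T1, a, m) + lnbMarginal(X2, r2 * T2, a, m)
    list(lsh = lsh, lin = lin,
         ll = sum(logSumExpPair(log1p(-th) + lsh, log(th) + lin)))
  }
  nllAlt <- function(par) {
    th <- 1 / (1 + exp(-par[1]))
    v <- exp(par[-1])
    out <- loglik_parts(th, v[1], v[2], v[3])$ll
    if (!is.finite(out)) return(1e10)
    -out
  }
  nllNull <- function(par) {
    v <- exp(par)
    out <- sum(lnbShared(X1, X2, T1, v[3] * T2, v[1], v[2]))
    if (!is.finite(out)) return(1e10)
    -out
  }
  m1hat <- max(mean(X1) / T1, 1e-4)
  m2hat <- max(mean(X2) / T2, 1e-4)
  lo0 <- c(log(1e-2), log(1e-8), log(1e-4))
  hi0 <- c(log(100), log(1e4), log(1e4))
  init0 <- c(log(1), log(m1hat), log(max(m2hat / m1hat, 1e-4)))
  nullFit <- nlminb(init0, nllNull, lower = lo0, upper = hi0)
  inits <- list(c(qlogis(0.3), nullFit$par),
                c(qlogis(0.05), nullFit$par),
                c(qlogis(0.7), init0))
  lo <- c(-12, lo0); hi <- c(12, hi0)
  best <- NULL
  for (init in inits) {
    f <- tryCatch(nlminb(init, nllAlt, lower = lo, upper = hi),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$objective < best$objective))
      best <- f
  }
  if (is.null(best)) stop("type-I optimizer failed")
  lnLAlt <- -best$objective
  lnLNull <- -nullFit$objective
  if (lnLAlt < lnLNull) lnLAlt <- lnLNull  # boundary th -> 0 nests the null

  th <- 1 / (1 + exp(-best$par[1]))
  v <- exp(best$par[-1])
  stat <- max(0, 2 * (lnLAlt - lnLNull))
  pval <- if (stat <= 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)

  H <- tryCatch(optimHess(best$par, nllAlt), error = function(e) NULL)
  se <- NA_real_
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && V[1, 1] > 0)
      se <- sqrt(V[1, 1]) * th * (1 - th)  # delta method from logit
  }

  parts <- loglik_parts(th, v[1], v[2], v[3])
  qk <- 1 / (1 + exp(log1p(-th) + parts$lsh - log(th) - parts$lin))
  if (th <= 1e-8) qk <- rep(0, n)
  post <- new("SitePosterior", qk = qk, cutoff = qkCutoff,
              flagged = which(qk > qkCutoff))
  est <- new("ThetaEstimate", type = "I", theta = th, se = se,
             lrtStat = stat, pValue = pval,
             aux = list(shape = v[1], meanRate1 = v[2], meanRate2 = v[2] * v[3],
                        lnLAlt = lnLAlt, lnLNull = lnLNull))
  list(theta = est, posterior = post)
}

logSumExpPair <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

## chance probability that a random single amino-acid substitution crosses
## property classes under the scheme
crossClassProb <- function(scheme = AA_CLASS_DEFAULT) {
  aa <- names(scheme)
  tot <- 0
  for (a in aa) tot <- tot + sum(scheme[a] != scheme[setdiff(aa, a)])
  tot / (length(aa) * (length(aa) - 1))
}

#' Type II functional divergence (constant-but-different model)
#'
#' Columns with a consensus residue in both clusters are classified as
#' conserved-identical, conserved-but-similar (different residue, same
#' physicochemical class) or conserved-but-different (radical class change).
#' theta II is the moment estimator of the excess of radical conserved
#' differences over the chance expectation; the chance rate is calibrated
#' from the observed same-class conserved differences (which genuine type-II
#' divergence does not generate) combined with the scheme's probability that
#' a random substitution crosses classes. Qk is the two-class posterior that
#' a column belongs to the constant-but-different state.
#'
#' @param aln protein \code{MsaAlignment}.
#' @param x rooted tree covering both clusters.
#' @param clusters a \code{clusterPair}.
#' @param scheme residue -> property-class map (default 5-class).
#' @param consensusThreshold majority fraction required for a cluster
#'   consensus (default 0.6); columns without consensus in either cluster are
#'   skipped as variable.
#' @param qkCutoff flagging cutoff (default 0.98).
#' @return list(theta = \code{ThetaEstimate}, posterior = \code{SitePosterior},
#'   classification = per-column character vector).
#' @export
estimateThetaII <- function(aln, x, clusters, scheme = AA_CLASS_DEFAULT,
                            consensusThreshold = 0.6, qkCutoff = 0.98) {
  stopifnot(is(aln, "MsaAlignment"), alphabetOf(aln) == "protein")
  m <- alignmentMatrix(aln)
  m1 <- m[clusters$cluster1, , drop = FALSE]
  m2 <- m[clusters$cluster2, , drop = FALSE]
  ncol_ <- ncol(m)

  consensusOf <- function(mm, j) {
    v <- mm[, j]
    v <- v[v %in% AA_LETTERS]
    if (!length(v)) return(NA_character_)
    tb <- sort(table(v), decreasing = TRUE)
    if (tb[1] / length(v) >= consensusThreshold) names(tb)[1] else NA_character_
  }
  c1 <- vapply(seq_len(ncol_), function(j) consensusOf(m1, j), "")
  c2 <- vapply(seq_len(ncol_), function(j) consensusOf(m2, j), "")

  cls <- rep("variable", ncol_)
  conserved <- !is.na(c1) & !is.na(c2)
  same <- conserved & c1 == c2
  diffres <- conserved & c1 != c2
  radical <- diffres & scheme[c1] != scheme[c2]
  cls[same] <- "conserved-identical"
  cls[diffres & !radical] <- "conserved-similar"
  cls[radical] <- "conserved-different"

  N <- sum(conserved)
  if (N == 0L) stop("theta II undefined: no conserved columns")
  ncd <- sum(radical)
  nsd <- sum(diffres & !radical)
  q0 <- crossClassProb(scheme)
  pChance <- min(0.999, (q0 / (1 - q0)) * (nsd / N))
  Fobs <- ncd / N
  th <- max(0, min(1, (Fobs - pChance) / (1 - pChance)))
  se <- sqrt(max(Fobs * (1 - Fobs) / N, 0)) / max(1 - pChance, 1e-9)

  ## binomial LRT of theta = 0 (boundary-aware)
  pAlt <- th + (1 - th) * pChance
  llAlt <- ncd * log(max(pAlt, 1e-12)) + (N - ncd) * log(max(1 - pAlt, 1e-12))
  llNull <- ncd * log(max(pChance, 1e-12)) + (N - ncd) * log(max(1 - pChance, 1e-12))
  stat <- max(0, 2 * (llAlt - llNull))
  pval <- if (stat <= 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)

  qk <- numeric(ncol_)
  if (th > 0) {
    qcd <- th / (th + (1 - th) * pChance)
    qk[radical] <- qcd
  }
  qk[!conserved] <- NA_real_
  post <- new("SitePosterior", qk = ifelse(is.na(qk), 0, qk), cutoff = qkCutoff,
              flagged = which(!is.na(qk) & qk > qkCutoff))
  est <- new("ThetaEstimate", type = "II", theta = th, se = se,
             lrtStat = stat, pValue = pval,
             aux = list(nConserved = N, nRadical = ncd, nSameClassDiff = nsd,
                        chanceRate = pChance, crossClassProb = q0))
  list(theta = est, posterior = post, classification = cls)
}

#' Map alignment columns to ungapped reference positions
#'
#' @param aln \code{MsaAlignment}.
#' @param refId row id of the reference sequence.
#' @return integer vector per column: 1-based position in the ungapped
#'   reference, NA where the reference has a gap.
#' @export
referenceCoordinateMap <- function(aln, refId) {
  m <- alignmentMatrix(aln)
  if (!refId %in% rownames(m)) stop("reference id not in alignment: ", refId)
  ref <- m[refId, ]
  isres <- !(ref %in% c(GAP, "?"))
  out <- rep(NA_integer_, length(ref))
  out[isres] <- cumsum(isres)[isres]
  out
}

#' Report sites exceeding the posterior cutoff
#'
#' @param post a \code{SitePosterior}.
#' @param cutoff posterior cutoff (default taken from \code{post}).
#' @param coordinateMap optional column -> reference-position map
#'   (see \code{referenceCoordinateMap}).
#' @param columns optional original column indices (when the posterior was
#'   computed on a filtered column subset).
#' @return data.frame: \code{column}, \code{refPosition}, \code{qk},
#'   \code{flagged}.
#' @export
flagDivergentSites <- function(post, cutoff = post@cutoff, coordinateMap = NULL,
                               columns = seq_along(post@qk)) {
  qk <- post@qk
  out <- data.frame(column = columns, refPosition = NA_integer_,
                    qk = qk, flagged = qk > cutoff)
  if (!is.null(coordinateMap)) out$refPosition <- coordinateMap[columns]
  out
}
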