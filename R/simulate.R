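## Seeded generators producing inputs with the statistical structure each
## analysis stage assumes: dated coalescent/birth-death trees, HKY alignments
## with epoch-varying kappa, branch-site codon alignments, two-cluster
## protein alignments with planted functional divergence, alignments with
## planted coevolving column pairs, and UTR sets with planted
## Shine-Dalgarno-like motifs. Every generator records the truth needed to
## score downstream recovery.

#' Derive a per-stage child seed from a global seed
#'
#' Deterministic fan-out so pipeline stages can be re-run independently:
#' child = (seed * 2654435761 + hash(stage)) mod (2^31 - 1), where hash is a
#' polynomial rolling hash of the stage name.
#'
#' @param seed integer global seed.
#' @param stage stage name.
#' @export
childSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 65536 * 32749 + h) %% 2147483647) + 1L
}

#' Simulate a time-calibrated tree with dated tips
#'
#' Coalescent mode draws tip times uniformly over \code{samplingWindow} years
#' (serial/heterochronous Kingman coalescent with effective size \code{Ne});
#' birth-death mode produces an isochronous tree conditioned on the number of
#' tips. Isochronous mode forces all tip dates equal.
#'
#' @param nTaxa number of tips (>= 3).
#' @param model \code{"coalescent"} or \code{"birth-death"}.
#' @param Ne coalescent effective size (years).
#' @param samplingWindow width of the sampling window in years.
#' @param isochronous force all tips to the latest date.
#' @param latestDate calendar year of the most recent tip.
#' @param birth,death birth-death rates (per year).
#' @param seed RNG seed.
#' @return a \code{TimedTree} (clocklike: branch lengths in years).
#' @export
simulateTimedTree <- function(nTaxa, model = c("coalescent", "birth-death"),
                              Ne = 30, samplingWindow = 100,
                              isochronous = FALSE, latestDate = 2020,
                              birth = 0.1, death = 0.05, seed = 1L) {
  model <- match.arg(model)
  stopifnot(nTaxa >= 3L)
  set.seed(seed)
  if (model == "birth-death") {
    tr <- ape::rphylo(nTaxa, birth, death)
    tr$tip.label <- paste0("t", seq_len(nTaxa))
    dates <- setNames(rep(latestDate, nTaxa), tr$tip.label)
    return(timedTree(tr, dates))
  }
  st <- if (isochronous) rep(0, nTaxa) else runif(nTaxa, 0, samplingWindow)
  st <- st - min(st)
  tr <- serialCoalescent(st, Ne)
  dates <- setNames(latestDate - st, paste0("t", seq_len(nTaxa)))
  tr$tip.label <- paste0("t", seq_len(nTaxa))
  timedTree(tr, dates)
}

## heterochronous Kingman coalescent; st = tip times (years before present)
serialCoalescent <- function(st, Ne) {
  n <- length(st)
  ord <- order(st)
  pending <- ord           # tip indices, by sampling time
  nodeTime <- c(st, rep(NA_real_, n - 1))
  nextInternal <- n + 1L
  active <- integer()
  Tcur <- 0
  edges <- matrix(0L, 0, 2)
  elen <- numeric()
  repeat {
    if (length(active) < 2L) {
      if (!length(pending)) break
      Tcur <- st[pending[1]]
      take <- pending[st[pending] <= Tcur + 1e-12]
      active <- c(active, take)
      pending <- setdiff(pending, take)
      next
    }
    k <- length(active)
    w <- rexp(1, k * (k - 1) / (2 * Ne))
    tNext <- if (length(pending)) st[pending[1]] else Inf
    if (Tcur + w >= tNext) {
      Tcur <- tNext
      take <- pending[st[pending] <= Tcur + 1e-12]
      active <- c(active, take)
      pending <- setdiff(pending, take)
    } else {
      Tcur <- Tcur + w
      pick <- sample(length(active), 2L)
      ch <- active[pick]
      nodeTime[nextInternal] <- Tcur
      edges <- rbind(edges, cbind(nextInternal, ch))
      elen <- c(elen, Tcur - nodeTime[ch])
      active <- c(active[-pick], nextInternal)
      nextInternal <- nextInternal + 1L
    }
    if (length(active) == 1L && !length(pending)) break
  }
  root <- active[1]
  ## renumber internals so the root is n+1 (ape convention)
  internals <- unique(edges[, 1])
  ord2 <- c(root, setdiff(internals[order(-nodeTime[internals])], root))
  newId <- integer(max(internals))
  newId[ord2] <- n + seq_along(ord2)
  e <- edges
  e[, 1] <- newId[e[, 1]]
  e[e[, 2] > n, 2] <- newId[e[e[, 2] > n, 2]]
  tr <- structure(list(edge = e, edge.length = elen,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = length(internals)),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

## generic discrete-state simulation down a tree; Pfun(edgeIndex) returns the
## transition matrix for that edge; returns tip states (ntip x nsites)
evolveStates <- function(tr, rootStates, Pfun) {
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  po <- rev(ape::postorder(tr))  # parents before children
  states <- matrix(0L, nnode, length(rootStates))
  root <- tr$edge[ape::postorder(tr)[length(ape::postorder(tr))], 1L]
  states[root, ] <- rootStates
  for (ed in po) {
    par <- tr$edge[ed, 1L]; ch <- tr$edge[ed, 2L]
    P <- Pfun(ed)
    old <- states[par, ]
    new <- integer(length(old))
    for (s in unique(old)) {
      idx <- which(old == s)
      new[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                             prob = P[s, ])
    }
    states[ch, ] <- new
  }
  states[seq_len(ntip), , drop = FALSE]
}

#' Simulate a DNA alignment under HKY with epoch-varying kappa
#'
#' Site-independent HKY evolution; each branch uses the kappa of its
#' temporal-midpoint epoch.
#'
#' @param x a \code{TimedTree}.
#' @param kappa numeric vector, one kappa per epoch (oldest first); length 1
#'   for a single-epoch model.
#' @param baseFreqs stationary base frequencies (A, C, G, T).
#' @param length alignment length (sites).
#' @param rate substitutions/site/year converting branch years to distance.
#' @param seed RNG seed.
#' @param partition optional \code{EpochPartition}; default
#'   \code{assignEpochs(x, length(kappa))}.
#' @return an \code{MsaAlignment} (dna).
#' @export
simulateDNA <- function(x, kappa, baseFreqs = rep(0.25, 4), length = 500L,
                        rate = 2e-3, seed = 1L,
                        partition = assignEpochs(x, max(length(kappa), 1L))) {
  set.seed(seed)
  tr <- treeOf(x)
  baseFreqs <- baseFreqs / sum(baseFreqs)
  epochOf <- partition@epochOf
  Pcache <- list()
  Pfun <- function(ed) {
    key <- paste(epochOf[ed], signif(tr$edge.length[ed], 12))
    if (is.null(Pcache[[key]])) {
      Q <- hkyMatrix(kappa[min(epochOf[ed], length(kappa))], baseFreqs)
      Pcache[[key]] <<- revPmat(Q, baseFreqs, tr$edge.length[ed] * rate)
    }
    Pcache[[key]]
  }
  root <- sample.int(4, length, replace = TRUE, prob = baseFreqs)
  tips <- evolveStates(tr, root, Pfun)
  m <- matrix(NT[tips], nrow(tips), dimnames = list(tr$tip.label, NULL))
  msaAlignment(m, "dna")
}

#' Simulate a codon alignment under the branch-site model
#'
#' Sites are assigned to the four model-A classes by the (p0, p1) weights;
#' foreground branches use omega2 for classes 2a/2b. Evolution uses exact
#' per-branch transition matrices (matrix exponentials of the same scaled
#' rate matrices the fitter uses).
#'
#' @param x a \code{TimedTree}.
#' @param kappa codon-level transition/transversion ratio.
#' @param omegaSpec list(p0, p1, omega0, omega2).
#' @param foreground integer foreground edge indices.
#' @param pi codon frequencies (61; default uniform).
#' @param nCodons alignment length in codons.
#' @param rate neutral substitutions/codon/year.
#' @param seed RNG seed.
#' @return list: \code{alignment} (codon \code{MsaAlignment}),
#'   \code{siteClasses} (1 = class 0, 2 = class 1, 3 = 2a, 4 = 2b).
#' @export
simulateCodon <- function(x, kappa = 2, omegaSpec = list(p0 = 0.5, p1 = 0.3,
                                                         omega0 = 0.1,
                                                         omega2 = 1),
                          foreground = integer(), pi = rep(1 / 61, 61),
                          nCodons = 300L, rate = 2e-3, seed = 1L) {
  set.seed(seed)
  tr <- treeOf(x)
  pi <- pi / sum(pi)
  w <- modelAWeights(omegaSpec$p0, omegaSpec$p1)
  cls <- sample.int(4, nCodons, replace = TRUE, prob = w)
  omegaBg <- c(omegaSpec$omega0, 1, omegaSpec$omega0, 1)
  omegaFg <- c(omegaSpec$omega0, 1, omegaSpec$omega2, omegaSpec$omega2)
  isFg <- seq_len(nrow(tr$edge)) %in% foreground
  Qcache <- list()
  tips <- matrix(0L, ape::Ntip(tr), nCodons)
  for (cl in sort(unique(cls))) {
    sites <- which(cls == cl)
    Pfun <- function(ed) {
      om <- if (isFg[ed]) omegaFg[cl] else omegaBg[cl]
      key <- paste(signif(om, 12), signif(tr$edge.length[ed], 12))
      if (is.null(Qcache[[key]])) {
        Q <- codonRateMatrix(kappa, om, pi)
        Qcache[[key]] <<- revPmat(Q, pi, tr$edge.length[ed] * rate)
      }
      Qcache[[key]]
    }
    root <- sample.int(61, length(sites), replace = TRUE, prob = pi)
    tips[, sites] <- evolveStates(tr, root, Pfun)
  }
  cods <- senseCodons()
  cm <- matrix(cods[tips], nrow(tips))
  m <- matrix("", nrow(cm), 3L * ncol(cm), dimnames = list(tr$tip.label, NULL))
  for (j in seq_len(ncol(cm))) {
    sp <- do.call(rbind, strsplit(cm[, j], ""))
    m[, (3L * j - 2L):(3L * j)] <- sp
  }
  list(alignment = msaAlignment(m, "codon"), siteClasses = cls)
}

#' Build a tree with two monophyletic clusters
#'
#' Two coalescent subtrees joined by stem branches at a common root; tips are
#' labelled \code{A1..} and \code{B1..}.
#'
#' @param n1,n2 cluster sizes.
#' @param Ne within-cluster coalescent size (years).
#' @param stem years between each cluster MRCA and the joint root.
#' @param latestDate calendar year of the most recent tip.
#' @param seed RNG seed.
#' @return list: \code{tree} (\code{TimedTree}), \code{cluster1},
#'   \code{cluster2}.
#' @export
twoClusterTree <- function(n1 = 8L, n2 = 8L, Ne = 20, stem = 30,
                           latestDate = 2020, seed = 1L) {
  set.seed(seed)
  t1 <- serialCoalescent(rep(0, n1), Ne)
  t2 <- serialCoalescent(rep(0, n2), Ne)
  t1$tip.label <- paste0("A", seq_len(n1))
  t2$tip.label <- paste0("B", seq_len(n2))
  h1 <- max(ape::node.depth.edgelength(t1))
  h2 <- max(ape::node.depth.edgelength(t2))
  ## equalize heights so the joint tree is a chronogram
  H <- max(h1, h2) + stem
  joint <- ape::read.tree(text = paste0(
    "(", sub(";$", "", ape::write.tree(t1)), ":", H - h1, ",",
    sub(";$", "", ape::write.tree(t2)), ":", H - h2, ");"))
  dates <- setNames(rep(latestDate, n1 + n2), joint$tip.label)
  list(tree = timedTree(joint, dates),
       cluster1 = t1$tip.label, cluster2 = t2$tip.label)
}

## Jukes-Cantor style k-state transition matrix
jcPmat <- function(k, d) {
  stay <- 1 / k + (k - 1) / k * exp(-k / (k - 1) * d)
  P <- matrix((1 - stay) / (k - 1), k, k)
  diag(P) <- stay
  P
}

#' Simulate two-cluster protein alignments with planted functional divergence
#'
#' Type I: a fraction \code{theta} of columns evolve with independent
#' gamma-distributed rates in the two cluster subtrees (rate shift); the rest
#' share one rate. Type II: a fraction \code{theta} of columns are constant
#' within each cluster but fixed for residues of different physicochemical
#' classes between clusters; the rest evolve slowly from a shared ancestral
#' residue.
#'
#' @param clusters result of \code{twoClusterTree} (or a \code{clusterPair}).
#' @param theta planted fraction in [0, 1].
#' @param type \code{"I"} or \code{"II"}.
#' @param shapeShared,shapeIndep gamma shapes of shared/independent rates.
#' @param meanRate mean substitution rate (per unit scaled branch length).
#' @param rate years -> branch-length scaling applied to the subtrees.
#' @param length number of columns.
#' @param scheme property classes (type II planting).
#' @param seed RNG seed.
#' @return list: \code{alignment} (protein \code{MsaAlignment}),
#'   \code{divergent} (logical truth per column).
#' @export
simulateDivergentClusters <- function(clusters, theta = 0.3,
                                      type = c("I", "II"),
                                      shapeShared = 0.5, shapeIndep = 0.5,
                                      meanRate = 1, rate = 0.02,
                                      length = 500L,
                                      scheme = AA_CLASS_DEFAULT, seed = 1L) {
  type <- match.arg(type)
  stopifnot(theta >= 0, theta <= 1)
  set.seed(seed)
  t1 <- if (!is.null(clusters$subtree1)) clusters$subtree1
        else ape::keep.tip(treeOf(clusters$tree), clusters$cluster1)
  t2 <- if (!is.null(clusters$subtree2)) clusters$subtree2
        else ape::keep.tip(treeOf(clusters$tree), clusters$cluster2)
  divergent <- runif(length) < theta
  n1 <- ape::Ntip(t1); n2 <- ape::Ntip(t2)
  m <- matrix("", n1 + n2, length,
              dimnames = list(c(t1$tip.label, t2$tip.label), NULL))
  evolveWithRates <- function(tr, rootStates, lam) {
    ntip <- ape::Ntip(tr)
    po <- rev(ape::postorder(tr))
    nnode <- ntip + tr$Nnode
    states <- matrix(0L, nnode, length(rootStates))
    root <- tr$edge[ape::postorder(tr)[length(ape::postorder(tr))], 1L]
    states[root, ] <- rootStates
    for (ed in po) {
      par <- tr$edge[ed, 1L]; ch <- tr$edge[ed, 2L]
      d <- tr$edge.length[ed] * rate * lam
      stay <- 1 / 20 + 19 / 20 * exp(-20 / 19 * d)
      old <- states[par, ]
      u <- runif(length(old))
      change <- u > stay
      new <- old
      if (any(change)) {
        shift <- sample.int(19L, sum(change), replace = TRUE)
        new[change] <- ((old[change] - 1L + shift) %% 20L) + 1L
      }
      states[ch, ] <- new
    }
    states[seq_len(ntip), , drop = FALSE]
  }
  if (type == "I") {
    root <- sample.int(20L, length, replace = TRUE)
    lamShared <- rgamma(length, shape = shapeShared,
                        rate = shapeShared / meanRate)
    lam1 <- ifelse(divergent,
                   rgamma(length, shape = shapeIndep, rate = shapeIndep / meanRate),
                   lamShared)
    lam2 <- ifelse(divergent,
                   rgamma(length, shape = shapeIndep, rate = shapeIndep / meanRate),
                   lamShared)
    m[t1$tip.label, ] <- AA_LETTERS[evolveWithRates(t1, root, lam1)]
    m[t2$tip.label, ] <- AA_LETTERS[evolveWithRates(t2, root, lam2)]
  } else {
    for (j in seq_len(length)) {
      if (divergent[j]) {
        r1 <- sample(AA_LETTERS, 1)
        pool <- AA_LETTERS[scheme != scheme[r1]]
        r2 <- sample(pool, 1)
        m[t1$tip.label, j] <- r1
        m[t2$tip.label, j] <- r2
      }
    }
    bg <- which(!divergent)
    if (length(bg)) {
      root <- sample.int(20L, length(bg), replace = TRUE)
      lam <- rgamma(length(bg), shape = shapeShared, rate = shapeShared / meanRate)
      m[t1$tip.label, bg] <- AA_LETTERS[evolveWithRates(t1, root, lam)]
      m[t2$tip.label, bg] <- AA_LETTERS[evolveWithRates(t2, root, lam)]
    }
  }
  list(alignment = msaAlignment(m, "protein"), divergent = divergent)
}

#' Simulate a protein alignment with planted coevolving column pairs
#'
#' Background columns evolve independently as a k-class Markov process on the
#' tree; each planted pair takes one class for all tips below a chosen
#' internal edge and another class elsewhere, in both columns, so the pair
#' co-segregates perfectly.
#'
#' @param x a \code{TimedTree}.
#' @param nBackground number of background columns.
#' @param nPlantedPairs number of planted pairs.
#' @param nClasses background state count (mapped onto residues of distinct
#'   property classes).
#' @param rate substitutions per year for the background process.
#' @param seed RNG seed.
#' @return list: \code{alignment} (protein), \code{truth} data.frame
#'   (column_i, column_j, edge).
#' @export
simulateCoevolvingAlignment <- function(x, nBackground = 30L,
                                        nPlantedPairs = 1L, nClasses = 5L,
                                        rate = 0.01, seed = 1L) {
  set.seed(seed)
  tr <- treeOf(x)
  ntip <- ape::Ntip(tr)
  ## one representative residue per property class
  reps <- c("A", "S", "K", "D", "F")[seq_len(nClasses)]
  Pfun <- function(ed) jcPmat(nClasses, tr$edge.length[ed] * rate)
  root <- sample.int(nClasses, nBackground, replace = TRUE)
  bg <- evolveStates(tr, root, Pfun)
  ncolTot <- nBackground + 2L * nPlantedPairs
  pos <- sample(ncolTot)   # shuffle column placement
  m <- matrix("", ntip, ncolTot, dimnames = list(tr$tip.label, NULL))
  m[, pos[seq_len(nBackground)]] <- reps[bg]
  below <- tipsBelowEdge(tr)
  sizes <- vapply(below, sum, 1L)
  ## plant on reasonably balanced splits so the co-segregation signal is
  ## resolvable against permutations of a 2-state column
  good <- which(sizes >= 4L & sizes <= ntip - 4L)
  if (!length(good)) good <- which(sizes >= 3L & sizes <= ntip - 3L)
  if (!length(good)) good <- which(sizes >= 2L & sizes <= ntip - 2L)
  truth <- data.frame(column_i = integer(), column_j = integer(),
                      edge = integer())
  for (p in seq_len(nPlantedPairs)) {
    ed <- if (length(good) == 1L) good else sample(good, 1L)
    cl <- sample(nClasses, 2L)
    i <- pos[nBackground + 2L * p - 1L]
    j <- pos[nBackground + 2L * p]
    for (col in c(i, j))
      m[, col] <- ifelse(below[[ed]], reps[cl[1]], reps[cl[2]])
    truth <- rbind(truth, data.frame(column_i = min(i, j),
                                     column_j = max(i, j), edge = ed))
  }
  list(alignment = msaAlignment(m, "protein"), truth = truth)
}

#' Simulate 5'UTR sets with planted Shine-Dalgarno-like motifs
#'
#' Each record is an annotated segment whose 5'UTR either carries the
#' canonical motif at a spacer drawn from \code{spacerProbs} ("canonical"),
#' carries no core match at all ("absent"), or is too short to scan ("NA").
#' Backgrounds avoid GG dinucleotides so that, at zero mutation rate, the
#' planted category is exactly recoverable. Point mutations are then applied
#' at \code{mutationRate} per base.
#'
#' @param n number of records.
#' @param sdFrequency planted canonical-motif frequency.
#' @param naFrequency fraction with an unscannable (short) 5'UTR.
#' @param spacerProbs named numeric over spacers 3..7.
#' @param mutationRate per-base mutation probability applied to the UTR.
#' @param utrLength background UTR length.
#' @param orfCodons length of the dummy ORF in codons (incl. start/stop).
#' @param seed RNG seed.
#' @return list: \code{segments} (named list of \code{annotatedSegment}),
#'   \code{truth} data.frame (strain_id, planted, spacer).
#' @export
simulateUTRSet <- function(n = 100L, sdFrequency = 0.6, naFrequency = 0.1,
                           spacerProbs = c(`3` = 0.1, `4` = 0.2, `5` = 0.4,
                                           `6` = 0.2, `7` = 0.1),
                           mutationRate = 0, utrLength = 25L, orfCodons = 6L,
                           seed = 1L) {
  stopifnot(sdFrequency + naFrequency <= 1, utrLength >= 14L)
  set.seed(seed)
  spacerProbs <- spacerProbs / sum(spacerProbs)
  spacerVals <- as.integer(names(spacerProbs))
  noGG <- function(len, prev = "") {
    out <- character(len)
    for (i in seq_len(len)) {
      pool <- if (prev == "G") c("A", "C", "T") else NT
      out[i] <- sample(pool, 1)
      prev <- out[i]
    }
    paste0(out, collapse = "")
  }
  orf <- paste0("ATG", paste(rep("GCT", orfCodons - 2L), collapse = ""), "TAA")
  cats <- sample(c("canonical", "absent", "NA"), n, replace = TRUE,
                 prob = c(sdFrequency, 1 - sdFrequency - naFrequency,
                          naFrequency))
  segments <- list()
  truth <- data.frame(strain_id = character(), planted = character(),
                      spacer = integer())
  for (i in seq_len(n)) {
    id <- sprintf("s%03d", i)
    sp <- NA_integer_
    if (cats[i] == "NA") {
      utr <- noGG(5L)
    } else if (cats[i] == "absent") {
      utr <- noGG(utrLength)
    } else {
      sp <- sample(spacerVals, 1, prob = spacerProbs)
      pre <- noGG(utrLength - 7L - sp)
      post <- noGG(sp, prev = "T")
      utr <- paste0(pre, SD_CANONICAL, post)
    }
    if (mutationRate > 0 && nchar(utr)) {
      ch <- strsplit(utr, "")[[1]]
      hit <- runif(length(ch)) < mutationRate
      if (any(hit))
        ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(NT, b), 1), "")
      utr <- paste0(ch, collapse = "")
    }
    s <- paste0(utr, orf)
    segments[[id]] <- annotatedSegment(s, data.frame(
      orf_name = "ORF1", start = nchar(utr) + 1L,
      end = nchar(utr) + nchar(orf)))
    truth <- rbind(truth, data.frame(strain_id = id, planted = cats[i],
                                     spacer = sp))
  }
  list(segments = segments, truth = truth)
}
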