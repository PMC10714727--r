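## Detection of coevolving residue pairs on a phylogeny after physicochemical
## alphabet reduction. A column's tree pattern is its partition of the tips
## into maximal monophyletic blocks of uniform reduced state; two columns
## co-segregate when their partitions agree. Significance is assessed by
## permuting states across tips within a column.

#' Reduce a protein alignment to property classes
#'
#' @param aln protein \code{MsaAlignment}.
#' @param scheme named character vector residue -> class covering all 20
#'   residues (e.g. \code{AA_CLASS_DEFAULT}, \code{AA_CLASS_IDENTITY}).
#' @return list: \code{classes} integer matrix (0-based class codes; gaps and
#'   X get their own code), \code{levels} class labels, \code{constant}
#'   logical per column (uniform or all-gap), \code{gapCode} the code used
#'   for gaps/unknowns.
#' @export
reduceAlphabet <- function(aln, scheme = AA_CLASS_DEFAULT) {
  stopifnot(is(aln, "MsaAlignment"), alphabetOf(aln) == "protein")
  miss <- setdiff(AA_LETTERS, names(scheme))
  if (length(miss))
    stop("scheme does not cover residues: ", paste(miss, collapse = ", "))
  m <- alignmentMatrix(aln)
  known <- m %in% names(scheme)
  bad <- setdiff(unique(as.vector(m[!known])), c("X", GAP, "?", "*"))
  if (length(bad)) stop("unknown residue symbol(s): ", paste(bad, collapse = " "))
  lev <- unique(unname(scheme))
  codes <- matrix(length(lev), nrow(m), ncol(m), dimnames = dimnames(m))
  codes[known] <- match(scheme[m[known]], lev) - 1L
  constant <- apply(codes, 2, function(v) length(unique(v[v < length(lev)])) <= 1L)
  list(classes = codes, levels = lev, constant = constant,
       gapCode = length(lev))
}

#' Tree pattern of one alignment column
#'
#' The partition of the tips into maximal monophyletic blocks within which
#' the column's (reduced) state is uniform; gaps count as their own state.
#'
#' @param col named vector of states (class codes or characters) by tip label,
#'   or a column index together with \code{reduced}.
#' @param x rooted tree (\code{TimedTree} or \code{phylo}).
#' @param reduced optional result of \code{reduceAlphabet} when \code{col}
#'   is a column index.
#' @return integer vector of 0-based block ids, named by tip label.
#' @export
columnTreePattern <- function(col, x, reduced = NULL) {
  tr <- if (is(x, "TimedTree")) treeOf(x) else x
  if (length(col) == 1L && is.numeric(col)) {
    stopifnot(!is.null(reduced))
    v <- reduced$classes[tr$tip.label, col]
  } else {
    v <- col[tr$tip.label]
    if (is.character(v)) v <- as.integer(factor(v)) - 1L
  }
  po <- ape::postorder(tr)
  edge <- tr$edge[po, , drop = FALSE]
  sig <- .cpp_column_signature(as.integer(v), edge, ape::Ntip(tr),
                               ape::Ntip(tr) + tr$Nnode)
  setNames(sig, tr$tip.label)
}

#' Detect coevolving column pairs
#'
#' Pair score = agreement of the two block partitions: 1 minus the transfer
#' distance (minimum number of tip moves turning one partition into the
#' other, computed exactly by optimal block matching) scaled by (ntip - 1).
#' Identical partitions score 1. Significance per pair by permuting the
#' second column's states across tips (\code{nPermutations} independent
#' draws); Benjamini-Hochberg correction across all pairs; retained pairs are
#' single-linkage clustered (connected components of the significant-pair
#' graph).
#'
#' @param reduced result of \code{reduceAlphabet}.
#' @param x rooted tree with tips matching the alignment.
#' @param nPermutations permutation draws per pair (>= 100).
#' @param alpha significance level on BH-adjusted p-values.
#' @param seed RNG seed.
#' @param columns optional column subset; default: all non-constant columns.
#' @param tieBreak \code{"conservative"} (ties between the observed and
#'   permuted scores count against significance; the standard, valid choice)
#'   or \code{"randomized"} (ties broken uniformly at random, giving exactly
#'   uniform null p-values; useful for calibration studies).
#' @return data.frame per pair (i < j, 1-based alignment coordinates):
#'   \code{column_i}, \code{column_j}, \code{score}, \code{pValue},
#'   \code{pAdjust}, \code{significant}, \code{cluster} (NA when not
#'   significant).
#' @export
detectCoevolvingPairs <- function(reduced, x, nPermutations = 1000L,
                                  alpha = 0.05, seed = 1L, columns = NULL,
                                  tieBreak = c("conservative", "randomized")) {
  tieBreak <- match.arg(tieBreak)
  if (nPermutations < 100L)
    stop("nPermutations must be at least 100 for usable p-value resolution")
  tr <- if (is(x, "TimedTree")) treeOf(x) else x
  if (is.null(columns)) columns <- which(!reduced$constant)
  if (length(columns) < 2L) stop("need at least 2 non-constant columns")
  states <- reduced$classes[tr$tip.label, columns, drop = FALSE]
  po <- ape::postorder(tr)
  edge <- tr$edge[po, , drop = FALSE]
  set.seed(seed)
  res <- .cpp_coevo_pairs(states, edge, ape::Ntip(tr) + tr$Nnode,
                          as.integer(nPermutations))
  nc <- length(columns)
  ii <- rep(seq_len(nc), times = nc)
  jj <- rep(seq_len(nc), each = nc)
  keep <- ii < jj
  idx <- cbind(ii[keep], jj[keep])
  g <- res$greater[idx]
  t0 <- res$ties[idx]
  pv <- if (tieBreak == "conservative") {
    (1 + g + t0) / (1 + nPermutations)
  } else {
    (g + runif(length(g)) * (t0 + 1)) / (1 + nPermutations)
  }
  out <- data.frame(
    column_i = columns[ii[keep]], column_j = columns[jj[keep]],
    score = res$score[idx],
    pValue = pv)
  out <- out[order(out$column_i, out$column_j), ]
  out$pAdjust <- stats::p.adjust(out$pValue, method = "BH")
  out$significant <- out$pAdjust <= alpha
  out$cluster <- NA_integer_
  if (any(out$significant)) {
    sig <- out[out$significant, c("column_i", "column_j")]
    nodes <- sort(unique(c(sig$column_i, sig$column_j)))
    parent <- setNames(nodes, as.character(nodes))  # union-find
    findRoot <- function(a) {
      while (parent[[as.character(a)]] != a) a <- parent[[as.character(a)]]
      a
    }
    for (r in seq_len(nrow(sig))) {
      ra <- findRoot(sig$column_i[r]); rb <- findRoot(sig$column_j[r])
      if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
    }
    roots <- vapply(nodes, findRoot, 1)
    ids <- setNames(match(roots, sort(unique(roots))), as.character(nodes))
    rowcl <- ids[as.character(out$column_i)]
    out$cluster[out$significant] <- rowcl[out$significant]
  }
  rownames(out) <- NULL
  out
}

#' Domain-level interaction weights
#'
#' Sums the scores of significant pairs into a symmetric domain x domain
#' matrix. Direct contributions come from the pairs themselves; indirect
#' contributions from two-step paths within a coevolution cluster (columns a
#' and b both significantly paired with a shared member c but not with each
#' other) contribute min(score(a,c), score(c,b)) to (domain(a), domain(b)),
#' counted once per shared member.
#'
#' @param pairs data.frame from \code{detectCoevolvingPairs}.
#' @param domains data.frame with columns \code{domain}, \code{start},
#'   \code{end} (1-based inclusive, non-overlapping); columns outside every
#'   range are pooled as "other".
#' @return symmetric numeric matrix of summed weights.
#' @export
summarizeWeights <- function(pairs, domains) {
  stopifnot(all(c("domain", "start", "end") %in% names(domains)))
  dd <- domains[order(domains$start), ]
  if (nrow(dd) > 1 && any(dd$start[-1] <= dd$end[-nrow(dd)]))
    stop("overlapping domain ranges")
  domainOf <- function(col) {
    hit <- which(col >= dd$start & col <= dd$end)
    if (length(hit)) dd$domain[hit[1]] else "other"
  }
  sig <- pairs[isTRUE1(pairs$significant), , drop = FALSE]
  cols <- sort(unique(c(sig$column_i, sig$column_j)))
  dmap <- setNames(vapply(cols, domainOf, ""), cols)
  doms <- sort(unique(c(dd$domain, dmap)))
  W <- matrix(0, length(doms), length(doms), dimnames = list(doms, doms))
  addW <- function(d1, d2, w) {
    W[d1, d2] <<- W[d1, d2] + w
    if (d1 != d2) W[d2, d1] <<- W[d2, d1] + w
  }
  keyOf <- function(a, b) paste(pmin(a, b), pmax(a, b))
  direct <- setNames(sig$score, keyOf(sig$column_i, sig$column_j))
  for (r in seq_len(nrow(sig)))
    addW(dmap[as.character(sig$column_i[r])],
         dmap[as.character(sig$column_j[r])], sig$score[r])
  ## indirect: two-step paths through a shared cluster member
  for (cl in unique(sig$cluster)) {
    sub <- sig[sig$cluster == cl, , drop = FALSE]
    members <- sort(unique(c(sub$column_i, sub$column_j)))
    adj <- lapply(setNames(members, members), function(mcol) {
      hits <- sub[sub$column_i == mcol | sub$column_j == mcol, , drop = FALSE]
      other <- ifelse(hits$column_i == mcol, hits$column_j, hits$column_i)
      setNames(hits$score, other)
    })
    for (c0 in members) {
      nb <- adj[[as.character(c0)]]
      if (length(nb) < 2) next
      cmb <- utils::combn(names(nb), 2)
      for (q in seq_len(ncol(cmb))) {
        a <- as.numeric(cmb[1, q]); b <- as.numeric(cmb[2, q])
        if (!is.na(direct[keyOf(a, b)])) next   # already a direct pair
        addW(dmap[as.character(a)], dmap[as.character(b)],
             min(nb[cmb[1, q]], nb[cmb[2, q]]))
      }
    }
  }
  W
}

isTRUE1 <- function(v) !is.na(v) & v
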