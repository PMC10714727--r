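## Accessors and show methods. Slots are implementation detail; downstream
## code goes through these.

#' @rdname TimedTree-class
#' @param object,x a \code{TimedTree}.
#' @export
setGeneric("tipDates", function(x) standardGeneric("tipDates"))

#' @rdname TimedTree-class
#' @export
setMethod("tipDates", "TimedTree", function(x) x@tipDates[x@tree$tip.label])

#' @rdname TimedTree-class
#' @export
setGeneric("treeOf", function(x) standardGeneric("treeOf"))

#' @rdname TimedTree-class
#' @export
setMethod("treeOf", "TimedTree", function(x) x@tree)

#' Node heights of a timed tree
#'
#' Heights in years before the most recent tip, derived from branch lengths:
#' height(node) = max tip depth - depth(node). For a calibrated chronogram the
#' height of tip i equals latest tip date minus the date of tip i.
#'
#' @param x a \code{TimedTree}.
#' @return numeric vector over all nodes (tips first, ape numbering).
#' @export
nodeHeights <- function(x) {
  stopifnot(is(x, "TimedTree"))
  dep <- ape::node.depth.edgelength(x@tree)
  max(dep[seq_len(ape::Ntip(x@tree))]) - dep
}

#' @rdname TimedTree-class
#' @export
latestTipDate <- function(x) {
  stopifnot(is(x, "TimedTree"))
  max(x@tipDates)
}

#' Calendar year of every node under the clock assumption
#'
#' @param x a \code{TimedTree}.
#' @return numeric vector of node dates (latest tip date minus node height).
#' @export
nodeDates <- function(x) latestTipDate(x) - nodeHeights(x)

#' Check strict time calibration
#'
#' TRUE when every tip's height (from branch lengths) matches the height
#' implied by its date, within \code{tol} years.
#'
#' @param x a \code{TimedTree}.
#' @param tol absolute tolerance in years.
#' @export
isChronogram <- function(x, tol = 1e-6) {
  h <- nodeHeights(x)[seq_len(ape::Ntip(x@tree))]
  expected <- latestTipDate(x) - tipDates(x)
  all(abs(h - unname(expected)) <= tol)
}

setMethod("show", "TimedTree", function(object) {
  n <- ape::Ntip(object@tree)
  d <- object@tipDates
  cat("TimedTree with", n, "tips\n")
  cat("  tip dates:", format(min(d), nsmall = 1), "-", format(max(d), nsmall = 1),
      if (length(unique(d)) == 1L) "(isochronous)\n" else "(heterochronous)\n")
  cat("  root height:", format(max(nodeHeights(object)), digits = 6), "years\n")
})

#' @rdname MsaAlignment-class
#' @param x a \code{MsaAlignment}.
#' @export
alignmentMatrix <- function(x) {
  stopifnot(is(x, "MsaAlignment"))
  x@seqs
}

#' @rdname MsaAlignment-class
#' @export
alphabetOf <- function(x) {
  stopifnot(is(x, "MsaAlignment"))
  x@alphabet
}

#' @rdname MsaAlignment-class
#' @export
sequenceIds <- function(x) rownames(alignmentMatrix(x))

#' @rdname MsaAlignment-class
#' @export
nSites <- function(x) ncol(alignmentMatrix(x))

#' Codon view of a codon alignment
#'
#' @param x a codon \code{MsaAlignment}.
#' @return character matrix of 3-letter codons (nseq x ncodon).
#' @export
codonMatrix <- function(x) {
  stopifnot(is(x, "MsaAlignment"), alphabetOf(x) == "codon")
  m <- alignmentMatrix(x)
  nc <- ncol(m) %/% 3L
  out <- matrix("", nrow(m), nc, dimnames = list(rownames(m), NULL))
  for (j in seq_len(nc)) {
    out[, j] <- paste0(m[, 3L * j - 2L], m[, 3L * j - 1L], m[, 3L * j])
  }
  out
}

setMethod("show", "MsaAlignment", function(object) {
  cat("MsaAlignment:", nrow(object@seqs), "sequences x", ncol(object@seqs),
      "columns (", object@alphabet, ")\n")
})

#' @rdname MarginalLikelihoodEstimate-class
#' @param x a \code{MarginalLikelihoodEstimate}.
#' @export
logML <- function(x) {
  stopifnot(is(x, "MarginalLikelihoodEstimate"))
  x@logML
}

#' @rdname MarginalLikelihoodEstimate-class
#' @export
mcSE <- function(x) {
  stopifnot(is(x, "MarginalLikelihoodEstimate"))
  x@mcSE
}

setMethod("show", "MarginalLikelihoodEstimate", function(object) {
  cat(sprintf("log marginal likelihood (%s): %.4f  (MC SE %.4f)\n",
              object@method, object@logML, object@mcSE))
})

setMethod("show", "BetsComparison", function(object) {
  cat("Heterochronous vs isochronous comparison (", object@convention, ")\n",
      sep = "")
  cat(sprintf("  log ML het: %.4f   log ML iso: %.4f\n",
              object@logMLHet, object@logMLIso))
  cat(sprintf("  Bayes factor: %.4f   favored: %s\n",
              object@bayesFactor, object@favored))
})

setMethod("show", "ClockFit", function(object) {
  cat("Root-to-tip regression (", object@rooting, " rooting)\n", sep = "")
  cat(sprintf("  rate: %.6g per year   tMRCA: %.2f   R^2: %.4f\n",
              object@rate, object@tmrca, object@rSquared))
})

setMethod("show", "BranchSiteFit", function(object) {
  cat("Branch-site model fit (", length(object@foreground),
      " foreground branches)\n", sep = "")
  cat(sprintf("  lnL alt: %.4f   lnL null: %.4f\n", object@lnLAlt, object@lnLNull))
  cat(sprintf("  omega2: %.3f   LRT: %.3f (df %g, p = %.4g)%s\n",
              object@params$omega2, object@lrtStat, object@df, object@pValue,
              if (isTRUE(object@significant)) "  *" else ""))
})

setMethod("show", "ThetaEstimate", function(object) {
  cat(sprintf("Type %s functional divergence: theta = %.3f (se %.3f), LRT %.3f, p = %.4g\n",
              object@type, object@theta, object@se, object@lrtStat, object@pValue))
})

setMethod("show", "SitePosterior", function(object) {
  cat(sprintf("Site posteriors over %d columns; %d flagged at Qk > %.2f\n",
              length(object@qk), length(object@flagged), object@cutoff))
})

setMethod("show", "EpochPartition", function(object) {
  cat(sprintf("EpochPartition: %d epochs of %g years; boundaries at %s\n",
              object@nEpochs, object@windowYears,
              paste(format(object@boundaries, digits = 6), collapse = ", ")))
})
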