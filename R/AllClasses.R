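#' @import methods
#' @importFrom stats optim optimize nlminb pchisq qchisq rnorm runif rexp rgamma
#'   rpois rbinom sd var lm coef quantile setNames residuals qlogis plogis
#'   pnorm dnorm optimHess rmultinom
#' @importFrom utils head tail read.delim write.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib parevol, .registration = TRUE
NULL

setOldClass("phylo")

## ---------------------------------------------------------------------------
## Central data containers
## ---------------------------------------------------------------------------

#' Time-calibrated rooted tree
#'
#' A rooted phylogeny whose branch lengths are measured in calendar years and
#' whose tips carry decimal-year sampling dates. Node heights (years before
#' the most recent tip) are derived from the branch lengths; for a strictly
#' clocklike (calibrated) tree the height of each tip equals the latest tip
#' date minus its own date.
#'
#' @slot tree a rooted \code{ape::phylo} object with non-negative branch
#'   lengths in years.
#' @slot tipDates named numeric vector of decimal calendar years, one per tip.
#' @export
setClass("TimedTree",
  representation(tree = "phylo", tipDates = "numeric"))

setValidity("TimedTree", function(object) {
  tr <- object@tree
  msgs <- character()
  if (!inherits(tr, "phylo")) msgs <- c(msgs, "tree must be a 'phylo' object")
  else {
    if (!ape::is.rooted(tr)) msgs <- c(msgs, "tree must be rooted")
    if (is.null(tr$edge.length)) msgs <- c(msgs, "tree must have branch lengths")
    else if (any(tr$edge.length < 0)) msgs <- c(msgs, "negative branch lengths")
    lbl <- tr$tip.label
    d <- object@tipDates
    if (is.null(names(d))) msgs <- c(msgs, "tipDates must be named")
    else {
      miss <- setdiff(lbl, names(d))
      if (length(miss) > 0L)
        msgs <- c(msgs, paste0("missing dates for tips: ",
                               paste(miss, collapse = ", ")))
      if (anyNA(d) || any(!is.finite(d))) msgs <- c(msgs, "non-finite tip dates")
      if (anyDuplicated(names(d))) msgs <- c(msgs, "duplicate names in tipDates")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Multiple sequence alignment
#'
#' Equal-length rows over a DNA, codon or amino-acid alphabet, stored as a
#' character matrix (one residue per cell, gap = \code{"-"}). Codon
#' alignments must have length divisible by three and contain no in-frame
#' stop codons.
#'
#' @slot seqs character matrix, rows = sequences (rownames are sequence ids),
#'   columns = alignment positions.
#' @slot alphabet one of \code{"dna"}, \code{"codon"}, \code{"protein"}.
#' @export
setClass("MsaAlignment",
  representation(seqs = "matrix", alphabet = "character"))

setValidity("MsaAlignment", function(object) {
  msgs <- character()
  if (!is.character(object@seqs)) msgs <- c(msgs, "seqs must be character")
  if (is.null(rownames(object@seqs))) msgs <- c(msgs, "seqs must have rownames")
  if (!object@alphabet %in% c("dna", "codon", "protein"))
    msgs <- c(msgs, "alphabet must be dna, codon or protein")
  if (object@alphabet == "codon" && ncol(object@seqs) %% 3L != 0L)
    msgs <- c(msgs, "codon alignment length not divisible by 3")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Temporal-signal results
## ---------------------------------------------------------------------------

#' Root-to-tip regression fit
#'
#' @slot rate substitution rate (distance units per year; OLS slope).
#' @slot tmrca calendar year at which the regression line crosses zero
#'   divergence (x-intercept).
#' @slot rSquared coefficient of determination of the regression.
#' @slot intercept OLS intercept (distance at year 0).
#' @slot residuals named per-tip residuals.
#' @slot rooting rooting criterion used.
#' @slot rootEdge index of the original edge on which the optimal root was
#'   placed (0 = original root retained).
#' @export
setClass("ClockFit",
  representation(rate = "numeric", tmrca = "numeric", rSquared = "numeric",
                 intercept = "numeric", residuals = "numeric",
                 rooting = "character", rootEdge = "integer"))

setValidity("ClockFit", function(object) {
  if (length(object@rSquared) == 1L &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
    return("rSquared outside [0,1]")
  TRUE
})

#' Power-posterior trace
#'
#' Log-likelihood samples collected at a ladder of power (beta) values, the
#' raw material of path-sampling and stepping-stone marginal-likelihood
#' estimators.
#'
#' @slot betas strictly increasing ladder in [0, 1] including both endpoints.
#' @slot samples list of numeric vectors of log-likelihood samples, one per
#'   rung, parallel to \code{betas}.
#' @export
setClass("PowerPosteriorTrace",
  representation(betas = "numeric", samples = "list"))

setValidity("PowerPosteriorTrace", function(object) {
  msgs <- character()
  b <- object@betas
  if (length(b) < 2L) msgs <- c(msgs, "need at least 2 rungs")
  if (any(diff(b) <= 0)) msgs <- c(msgs, "betas must be strictly increasing")
  if (length(b) && (b[1] < 0 || b[length(b)] > 1))
    msgs <- c(msgs, "betas must lie in [0,1]")
  if (length(object@samples) != length(b))
    msgs <- c(msgs, "one sample vector required per rung")
  if (any(vapply(object@samples, length, 1L) < 1L))
    msgs <- c(msgs, "every rung needs at least one sample")
  if (length(msgs)) msgs else TRUE
})

#' Log marginal-likelihood estimate
#'
#' @slot method \code{"PS"} (path sampling) or \code{"SS"} (stepping stone).
#' @slot logML estimated log marginal likelihood.
#' @slot mcSE Monte-Carlo standard error (block bootstrap).
#' @export
setClass("MarginalLikelihoodEstimate",
  representation(method = "character", logML = "numeric", mcSE = "numeric"))

setValidity("MarginalLikelihoodEstimate", function(object) {
  msgs <- character()
  if (!object@method %in% c("PS", "SS")) msgs <- c(msgs, "method must be PS or SS")
  if (!is.finite(object@logML)) msgs <- c(msgs, "logML must be finite")
  if (object@mcSE < 0) msgs <- c(msgs, "mcSE must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Heterochronous-vs-isochronous model comparison
#'
#' @slot logMLHet,logMLIso log marginal likelihoods of the two models.
#' @slot bayesFactor log-scale Bayes factor under the chosen convention.
#' @slot favored \code{"heterochronous"}, \code{"isochronous"} or
#'   \code{"inconclusive"}.
#' @slot convention \code{"table1"} (iso - het) or \code{"log-bf"} (het - iso).
#' @slot threshold decision threshold on the Bayes-factor scale.
#' @export
setClass("BetsComparison",
  representation(logMLHet = "numeric", logMLIso = "numeric",
                 bayesFactor = "numeric", favored = "character",
                 convention = "character", threshold = "numeric"))

## ---------------------------------------------------------------------------
## Epoch / selection results
## ---------------------------------------------------------------------------

#' Epoch partition of a timed tree
#'
#' Fixed-width calendar windows stepped back from the latest tip date; every
#' branch is assigned the epoch of its temporal midpoint and also carries the
#' exact fraction of its span falling in each epoch.
#'
#' @slot boundaries calendar years separating epochs (increasing; length
#'   nEpochs - 1).
#' @slot epochOf integer epoch id per edge (named by child node id); epoch 1
#'   is the oldest.
#' @slot fractions edges x epochs matrix of time fractions (rows sum to 1).
#' @slot nEpochs,windowYears partition parameters.
#' @slot latestDate calendar year of the most recent tip.
#' @export
setClass("EpochPartition",
  representation(boundaries = "numeric", epochOf = "integer",
                 fractions = "matrix", nEpochs = "integer",
                 windowYears = "numeric", latestDate = "numeric"))

setValidity("EpochPartition", function(object) {
  msgs <- character()
  if (any(diff(object@boundaries) <= 0))
    msgs <- c(msgs, "boundaries must be strictly increasing")
  rs <- rowSums(object@fractions)
  if (length(rs) && any(abs(rs - 1) > 1e-8))
    msgs <- c(msgs, "per-branch epoch fractions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Branch-site codon model fit
#'
#' Alternative (free foreground omega2 >= 1) and null (omega2 = 1) fits of
#' the four-class branch-site mixture, with the likelihood-ratio test.
#'
#' @slot foreground integer vector of foreground edge indices.
#' @slot lnLAlt,lnLNull maximized log-likelihoods.
#' @slot params named list: p0, p1, omega0, omega2, kappa, scale (alternative
#'   model MLEs).
#' @slot nullParams same for the null model.
#' @slot lrtStat,df,pValue likelihood-ratio test.
#' @slot significant logical at the configured alpha.
#' @export
setClass("BranchSiteFit",
  representation(foreground = "integer", lnLAlt = "numeric", lnLNull = "numeric",
                 params = "list", nullParams = "list", lrtStat = "numeric",
                 df = "numeric", pValue = "numeric", significant = "logical"))

## ---------------------------------------------------------------------------
## Functional divergence results
## ---------------------------------------------------------------------------

#' Functional-divergence coefficient estimate
#'
#' @slot type \code{"I"} or \code{"II"}.
#' @slot theta coefficient in [0, 1].
#' @slot se standard error (observed information; NA when unavailable).
#' @slot lrtStat,pValue boundary-aware test of theta = 0.
#' @slot aux named list of auxiliary rate parameters.
#' @export
setClass("ThetaEstimate",
  representation(type = "character", theta = "numeric", se = "numeric",
                 lrtStat = "numeric", pValue = "numeric", aux = "list"))

setValidity("ThetaEstimate", function(object) {
  msgs <- character()
  if (object@theta < -1e-9 || object@theta > 1 + 1e-9)
    msgs <- c(msgs, "theta outside [0,1]")
  if (is.finite(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msgs <- c(msgs, "pValue outside [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Site-specific posterior probabilities
#'
#' @slot qk per-column posterior probability of the divergent class.
#' @slot cutoff flagging cutoff (default 0.98).
#' @slot flagged integer indices (1-based alignment columns) with qk > cutoff.
#' @export
setClass("SitePosterior",
  representation(qk = "numeric", cutoff = "numeric", flagged = "integer"))

setValidity("SitePosterior", function(object) {
  if (length(object@qk) && (min(object@qk, na.rm = TRUE) < -1e-12 ||
                            max(object@qk, na.rm = TRUE) > 1 + 1e-12))
    return("qk outside [0,1]")
  TRUE
})
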