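---
title: "Models and methods in parevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in parevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parevol)
```

`parevol` bundles the statistical machinery needed to ask whether a set of
viral lineages — the motivating case is the three picobirnavirus species and
their suspected dual (reovirus-like and partitivirus-like) ancestry — evolved
in parallel: is there a measurable molecular clock; when and on which
branches did episodic positive selection act relative to the mutational bias
of each era; which residues shifted their evolutionary regime between
lineages; which residue pairs coevolve; and do upstream Shine-Dalgarno-like
motifs behave like functional signals or like decaying vestiges. This
vignette states each model, its assumptions and tunable parameters, the
numerical choices, and what the synthetic-data experiments do and do not
establish.

## Timed trees, coordinates, missing data

The central container is a rooted tree with branch lengths in calendar years
and decimal-year tip dates (`TimedTree`). Node heights are measured in years
before the most recent tip; for a strict chronogram a tip's height equals the
latest date minus its own date, and `readTimedTree(calibrated = TRUE)`
asserts this to a tolerance (default 1e-6 years). Trees used only for
root-to-tip regression may violate it (divergence trees are not clocks).
Dates are read from a `name_YYYY[.fraction]` suffix after the last underscore
or from a sidecar table, the table taking precedence.

All user-facing site and residue coordinates are 1-based inclusive; internal
arrays are 0-based. DNA ambiguity codes and gaps enter likelihoods as missing
data; codon columns containing any gap or ambiguity are excluded from codon
likelihoods entirely.

## Temporal signal

**Root-to-tip regression.** Divergence from the root is regressed on
sampling date by ordinary least squares; the slope estimates the
substitution rate and the x-intercept the root date (tMRCA). Because
root-to-tip distances are linear in the root position along any single
branch, both rooting criteria (maximal R-squared and minimal residual mean
square) have closed-form per-branch optima; the search is exact, over every
branch, with ties broken toward the smallest edge index. Isochronous tips
leave the regression undefined and raise an error.

**Marginal-likelihood estimators.** Given log-likelihood samples at a power
ladder beta in [0,1] (a `PowerPosteriorTrace`), path sampling integrates the
per-rung mean log-likelihood over beta by the trapezoid rule, and stepping
stone sums log mean importance ratios between adjacent rungs (using the lower
rung's samples, log-sum-exp stabilized). The default ladder has K = 50 rungs
at Beta(0.3, 1)-quantile spacing, concentrating rungs near beta = 0 where the
integrand changes fastest. Monte-Carlo standard errors use a block bootstrap
(blocks of 50 consecutive samples, 200 replicates, an internal fixed seed
that does not disturb the caller's RNG) so that autocorrelated MCMC traces
are not over-trusted. Both estimators are exact for beta-independent
likelihoods. On the conjugate normal test model (known variance, normal
prior on the mean — the standard closed-form oracle) both land within a few
Monte-Carlo SE of the analytic value; note that path sampling also carries a
deterministic quadrature bias that shrinks only as the ladder grows (about
0.01 log units at 50 rungs for that model), which is why the convergence
experiment doubles rungs and samples together.

**Heterochronous vs isochronous comparison.** `betsCompare` exposes two
orientations of the log Bayes factor. The `table1` convention reports
`logml_iso - logml_het`, which is the orientation that reproduces published
BETS tables in which positive printed values accompany support for the
heterochronous model; `log-bf` reports `logml_het - logml_iso`. Under either
convention the decision rule is symmetric: above +3 favors heterochronous,
below -3 favors isochronous, otherwise inconclusive. Whether such printed
values are Kass-Raftery log Bayes factors is not asserted; the arithmetic is
reproduced as printed.

**Desk-scale BETS harness.** `runBetsToy` runs adaptive random-walk
Metropolis at every rung (visited from beta = 1 down to 0 with warm starts;
proposals tuned toward 30% acceptance during burn-in) and flags rungs with
effective sample size below 50. The built-in clock model is a regression of
root-to-tip distances on dates with a free divergence level at the latest
date, an exponential prior (mean 0.003/year) on the non-negative rate, and a
lognormal prior on the noise SD. The free level and the exponential rate
prior matter: they let the model collapse to a no-clock constant-mean fit
when dates carry no signal, so that permuting the dates yields |log BF| < 3
rather than a spurious penalty, while genuinely clocklike data give log BF
well above 3. The headline estimator is stepping stone, which is more stable
than path sampling when the prior is diffuse.

## Epochs, kappa, and adaptive divergence

`assignEpochs` cuts time into windows of 50 years (default, configurable)
anchored at the latest tip date; the oldest epoch absorbs everything beyond
the last boundary. Branches are assigned categorically by their temporal
midpoint — the simplest deterministic rule — and the exact fraction of each
branch in each epoch is also reported for sensitivity analyses (the
fractions reconstruct every branch length to 1e-9).

`estimateEpochKappa` fits HKY with empirical base frequencies, one free
kappa per epoch (branches mapped by midpoint) and one free rate scaling of
the year-unit branch lengths, by maximum likelihood via Felsenstein pruning
on compressed site patterns. This is the maximum-likelihood analogue of
estimating per-epoch transition/transversion bias inside a Bayesian epoch
model: deterministic, fast, and testable against a matrix-exponential
oracle. Standard errors come from the observed-information diagonal on the
log scale. Epochs without branches yield NA with a warning.

The branch-site model is the standard four-class mixture: class 0 (omega0 in
(0,1) everywhere), class 1 (neutral), classes 2a/2b (omega0 or 1 on
background, a shared omega2 >= 1 on pre-specified foreground branches), with
weights p0, p1, p2*p0/(p0+p1), p2*p1/(p0+p1). Rates follow a GY94-style
codon matrix (single-nucleotide exchanges, kappa, target-codon frequencies;
F3x4 default, F1x4 and equal available) over the 61 sense codons, scaled so
one unit of branch length is one expected substitution per codon for a
neutral site — site classes keep their relative speeds under a shared
scaling, and the generator uses the same convention. Likelihoods are
computed in compiled code by pruning; parameters are optimized on an
unconstrained scale (softmax proportions, logit omega0, log rates) with a
deterministic first start, optional jittered restarts, and the alternative
warm-started from the null so the fits stay nested (lnL_alt >= lnL_null by
construction). The LRT uses a plain chi-square with 1 df as the primary
reference (`lrtReference = "mixture"` gives the 50:50 boundary mixture);
the null omega2 = 1 makes the test conservative in practice, and the null
calibration experiment checks rejection <= 0.08 at alpha = 0.05.

Adaptive divergence per 50-year window is the sum of estimated foreground
omega2 over branches with statistical support (p < 0.05 and omega2 > 1,
configurable) whose midpoint falls in the window, divided by the window
epoch's kappa. Where the source material describes the combination once as
"adding" and once as "dividing", the division form is implemented: AD =
sum(omega2)/kappa, which makes AD exactly halve when every kappa doubles.
Windows with no supported branch score 0; a missing kappa for a window that
needs one is an error.

## Functional divergence

**Counts.** `countSiteChanges` computes Fitch parsimony minimum changes per
column within each cluster's subtree (clusters must be monophyletic, >= 4
taxa each; gaps are missing data). Counts never exceed taxa - 1 per cluster.

**Type I.** The model is a two-state mixture over columns: with probability
1 - theta the column's rate lambda is shared by both clusters; with
probability theta the clusters draw independent rates. Both states draw from
the *same* gamma (free shape and mean), and a per-cluster mean multiplier
absorbs systematic rate differences in both states. This constraint is
deliberate: with fully free per-state gammas the mixture is unidentifiable
(the "shared" and "independent" labels can swap, and in pilot fits they did,
sending flagged sites to the wrong columns). Marginals are closed-form
negative-binomial (shared: one gamma integrated against both Poisson counts;
independent: a product of univariate forms). Qk is the posterior probability
of the independent-rate state; theta = 0 sits on the boundary, so the LRT
p-value uses the 50:50 mixture of chi-square 0 and 1.

Parsimony counts are a lossy channel: per-branch censoring (at most one
visible change per branch per column) and ancestral reassignment compress
the upper tail, which deflates the apparent rate variance and biases theta
downward. `estimateThetaI` therefore calibrates, per subtree, the expected
Fitch count as a function of the true expected substitution load (a short
simulation over a log-spaced grid, fixed internal seed, monotone
interpolation) and maps observed counts back through the inverse curve
before applying the likelihood. `channelCorrection = "none"` disables this.

**Type II.** Columns with a >= 60% majority consensus in both clusters are
classified conserved-identical, conserved-but-similar (different residue,
same physicochemical class) or conserved-but-different (radical class
change) under a configurable scheme (default 5 classes: nonpolar, polar,
positive, negative, aromatic). theta II is the moment estimator of the
excess of radical conserved differences over chance. The chance rate is
calibrated from the data themselves: genuine constant-but-different
divergence does not generate same-class conserved differences, so the
observed same-class difference rate, combined with the scheme's probability
that a random substitution crosses classes, fixes the expected chance level
without needing branch lengths on a substitution scale. Qk is the two-class
posterior that a conserved-different column belongs to the divergent state.
No conserved columns at all is an error ("theta II undefined").

**Reporting.** `flagDivergentSites` emits flagged sites in both alignment
coordinates and ungapped reference coordinates via
`referenceCoordinateMap`, with the 0.98 cutoff as the default.

## Coevolving pairs

Residues are first recoded by physicochemical class (`AA_CLASS_DEFAULT`,
identity and charge schemes included; gaps keep their own code). A column's
tree pattern is the partition of the tips into maximal monophyletic blocks
of uniform reduced state. The pair score is 1 minus the transfer distance
between the two partitions (minimum tip moves, computed exactly by a
Hungarian assignment on the block-overlap matrix) scaled by (ntip - 1):
identical partitions score 1. This block-partition formulation is inspired
by, but not identical to, published tree-based coevolution scanners whose
exact scoring is specified only by citation; it captures the same use —
significant pair lists and domain-level weights — with a fully reproducible,
oracle-testable score.

Significance is per pair, by permuting the second column's states across the
tips (independent draws per pair, at least 100; default 1000), with
Benjamini-Hochberg correction across pairs and single-linkage clustering of
the survivors. Two caveats are built into the design. First, tied scores
make standard permutation p-values conservative; `tieBreak = "randomized"`
yields exactly uniform null p-values for calibration studies, while the
default remains the conservative count. Second, two columns evolved
independently *on the same tree* share phylogenetic structure, so tip
permutation is a null for "more co-segregation than random labels", not
"more than the tree alone explains" — the null calibration experiment
therefore uses iid-random alignments, and significant pairs on real data
should be read as co-segregation calls, with the tree as a known confounder.

Domain weights sum the scores of significant pairs into a symmetric domain
by domain matrix (columns outside every annotated range pool as "other");
indirect contributions add min(score(a,c), score(c,b)) for two-step paths
through a shared cluster member c when (a,b) is not itself significant,
counted once per shared member.

## Shine-Dalgarno-like motifs

`annotatedSegment` validates ORFs (ATG start, stop end, length divisible by
3, non-overlapping) and `extractRegions` derives the 5'UTR, intergenic
region(s) and 3'UTR. `scanSD` searches the window in which a 7-mer ends
5 +/- 2 nt upstream of the start codon (configurable center and tolerance):
a window equal to the canonical AGGAGGU (U and T are interchangeable
throughout) is canonical; a window with G at core positions 2, 3, 5, 6
(xGGxGGx; `maxCoreMismatch` relaxes this) is a variant; no match is absent;
a region shorter than 7 plus the minimal spacer is NA. When several windows
match, canonical beats variant, then the spacer closest to 5 wins, ties
toward the shorter spacer. Position entropies are Shannon entropies in bits
over the observed bases (no pseudocounts; 0 to 2 by construction), and a
motif group is "stable" when its mean positional entropy is at most 0.5 bits
— a configurable default, chosen because it corresponds to roughly one
intermittently variable position out of seven. Secondary structure and
anti-SD pairing energies are out of scope.

## Synthetic data: what it shows and what it does not

All generators are seeded and bit-reproducible; `childSeed` derives
per-stage streams from one global seed by a fixed rolling-hash formula.
Trees come from a serial (heterochronous) Kingman coalescent — tip times
uniform over the sampling window, coalescence at rate k(k-1)/2Ne — or a
birth-death process conditioned on n (isochronous); the isochronous
coalescent root age matches the 2Ne(1 - 1/n) expectation. Sequence
generators use exact per-branch transition matrices (eigendecompositions of
the same scaled rate matrices the estimators use), not event-level
simulation, so generator and fitter agree to numerical precision and
matrix-exponential oracles apply directly.

Study-scale defaults were fixed once per experiment: branch-site power runs
on 8-taxon trees sampled over 60 years, neutral divergence 8e-3
substitutions/codon/year (about 2.7e-3 per site per year, the fast end of
the RNA-virus range), the longest internal branch as the pre-specified
foreground, omega2 = 6 on 300 codons (nulls use 100 codons); type-I
recovery uses two 96-taxon clusters (total subtree load about 2-4 expected
substitutions per unit rate, thin branches so the parsimony channel stays
nearly linear), theta = 0.3 over 800 columns with gamma shape 0.5; the
coevolution experiment plants one pair on an internal edge with at least 4
tips on each side among 30 background columns on 12 taxa — a 3-tip split is
intrinsically at the resolution limit of a 1000-draw permutation test.

Passing these experiments shows the estimators recover the structures they
model, at realistic desk scales, from data generated under those models. It
does not show robustness to alignment error, recombination or reassortment,
selection models outside the four-class mixture, non-monophyletic clusters,
rate variation beyond a single gamma, or the tree-shaped confounding of
coevolution scores on real alignments. Tree inference itself, Bayesian
epoch MCMC, site-level identification of selected codons, and RNA secondary
structure are intentionally out of scope; trees are inputs here.

## Numerical choices

Likelihood optimizations use `nlminb` on unconstrained transforms with
bounded parameter ranges and deterministic first starts; branch-site fits
add jittered restarts under a local RNG so the caller's stream is never
touched. Reversible rate matrices are exponentiated through symmetric
eigendecompositions with negative rounding clipped at zero; pruning rescales
partial likelihoods when they underflow 1e-120. Degenerate inputs fail
loudly: isochronous tips in the regression, single-rung ladders, all-zero
substitution counts, clusters that are not monophyletic, overlapping ORFs
or domains, permutation counts below 100.
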