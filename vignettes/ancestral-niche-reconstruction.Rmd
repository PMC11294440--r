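---
title: "Methods: from occurrence records to ancestral climatic tolerances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from occurrence records to ancestral climatic tolerances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ancniche` asks how the climatic niches of a small clade evolved: which
climate variables delimit each species' range today, and what climatic
tolerances their common ancestors plausibly held. The pipeline chains
five stages that are common currency in ecological niche modelling and
phylogenetic comparative methods, each usable on its own.

## The modelling chain

**1. Occurrences.** Presence records (`species,lon,lat`, WGS84) are
spatially thinned so that no two retained points of a species lie
within a minimum distance of one another (default 1 km). Thinning
removes the pseudo-replication created by roadside and streamside
sampling; it is a maximum-independent-set problem, and the
implementation uses greedy highest-degree deletion with random
tie-breaks, several restarts, and a final repair pass that guarantees
the retained set is *maximal* (every removed point lies within the
radius of a retained one). Thinning is per-species by default - each
species' model sees its own sampling bias - with a `pool = TRUE`
escape hatch.

**2. Pseudo-absences.** The models are presence/background
classifiers: each species receives pseudo-absences equal in number to
its thinned presences, drawn uniformly without replacement from
non-masked grid cells that contain no presence. Excluding presence
cells avoids handing the classifier contradictory labels for one cell;
everything else about the background is deliberately uninformed.

**3. Predictors.** Climate layers live on one shared grid with a
shared nodata mask (a cell missing anywhere is masked everywhere).
Pairwise Pearson correlations are computed over all non-masked cells
of the study extent, and while any pair exceeds |r| = 0.75 the
variable with the largest mean absolute correlation to the remaining
ones is dropped (ties drop the later variable, so the order of the
input stack is a documented preference ranking). The whole-extent
evaluation domain makes pruning species-independent, which the
downstream overlap statistics need.

**4. Ensemble niche models.** Four families are fitted per species on
the standardised covariates:

| family | form | notes |
|---|---|---|
| GLM | logistic regression, linear + quadratic terms | the quadratic is the log of a Gaussian response |
| GAM | binomial additive model, cubic regression splines (~4 df) | REML smoothing |
| GBM | gradient-boosted trees, 100 trees, depth 3, eta 0.1 | single-threaded for exact reproducibility |
| MAXENT_S | L1-regularised logistic on linear + quadratic + pairwise products | a transparent surrogate for MaxEnt's feature machinery |

Small presence/absence tables with clean climatic separation push
unpenalised likelihoods to complete or quasi-separation: coefficients
diverge, held-out scores saturate at exactly 0 and 1, and the
direction of divergence is partly set by uninformative covariates.
When the GLM or GAM fit shows separation symptoms (non-convergence, a
standardised coefficient beyond 15, or a linear predictor beyond 30 in
absolute value) it is refitted with a light ridge penalty - on the
same quadratic features for the GLM, on an additive natural-spline
basis for the GAM, so each family keeps its character. The same ridge
path serves tables with fewer rows than features.

Performance is estimated by repeated stratified splits (default 70%
training, 5 repeats): AUC from the rank-based Mann-Whitney statistic
with midrank ties, and Cohen's kappa and the true skill statistic
(TSS = sensitivity + specificity - 1) at the threshold that maximises
TSS on the held-out scores (candidate thresholds are midpoints of
consecutive unique scores plus 0 and 1; ties return the smallest).
The consensus map is the cell-wise TSS-weighted mean of member
predictions, restricted to members with TSS at or above 0.7 - the
usual consensus-modelling convention; both knobs sit in
`pipeline_config()`. Variable contributions are permutation
importances: the mean drop in training AUC over 10 seeded permutations
of each column, clipped at zero and rescaled to percentages.

**5. Predicted niche occupancy and ancestral tolerances.** Each
climate variable's range over the study extent is cut into 100
equal-interval bins (last bin right-closed), and bin *k* of a species'
PNO receives the summed ensemble suitability of the cells whose value
falls in bin *k*, normalised to a probability vector. Binning over the
*global* extent, not per species, keeps all species' profiles on one
support so that Schoener's D (`1 - 0.5 * sum |p - q|`) and the
Hellinger-based I (`1 - H^2/2`) are well defined.

The chronogram (Newick, branch lengths in Ma, ultrametric within a
configurable tolerance) is pruned to one terminal per species; when
the kept tips' MRCA lies below the original root, the stem is retained
as the tree's root edge so no time is silently discarded. Ancestral
tolerances follow the classic resampling scheme: for each of
`n_pno_samples` (default 100) replicates, one climate value is drawn
per tip from its PNO and maximum-likelihood Brownian-motion ancestral
states are computed; each internal node is summarised by the
across-sample mean, SD and equal-tail 80% interval. The BM rate is
re-estimated inside every replicate rather than fixed, so rate
uncertainty propagates. Tips are summarised from the PNO itself: the
suitability-weighted mean and the 80% equal-tail central density.

## The Brownian-motion machinery

Tip values are modelled as multivariate normal with mean `root * 1`
and covariance `sigma^2 * C`, `C[i, j]` the shared root-to-MRCA path
length of tips i and j. The fit is the GLS root
`(1'C^-1 z)/(1'C^-1 1)` and the ML rate `Q/n`, but neither `C` nor its
inverse is ever formed: a postorder pruning pass folds child messages
pairwise, accumulating the quadratic form and log-determinant, in
linear time. Ancestral states add a preorder pass that propagates the
information from the rest of the tree down each branch; combining the
upward and downward messages at a node is equivalent to re-rooting the
tree there and reading off the root estimate. Zero-length branches
act as exact pins (a tip on a zero branch fixes its node); a fold of
two zero-variance messages with different values is a degenerate
covariance and is rejected. The test suite checks both passes against
an explicit dense-matrix GLS oracle and against an independent
re-rooting implementation to 1e-8.

Two corners are worth knowing: identical tip values give `sigma^2 = 0`
and an unbounded likelihood (reported as `Inf`); and non-ultrametric
trees are accepted by `bm_mle()` (the GLS formula does not need
ultrametricity) but rejected by `node_ages()` and hence by the
tolerance reconstruction, which needs a time axis.

## What the synthetic generator emulates, and what it does not

Real inputs for this kind of study - curated occurrence records,
WorldClim-style bioclim rasters, a dated tree from a Bayesian relaxed
clock - cannot be bundled or downloaded at test time, so the package
carries a generator whose outputs exercise every stage with known
ground truth:

* **Climate layers** are planar gradients plus three low-frequency
  sinusoids plus smoothed noise, rescaled to realistic per-variable
  ranges. Gradient directions are spread evenly across variables so
  chance inter-layer correlations stay modest, and one engineered pair
  (the two precipitation-variability analogues) shares a latent field
  at r = 0.95 to exercise the pruning rule.
* **Species** have Gaussian niches on two informative variables
  (annual-mean-temperature and wettest-month-precipitation analogues).
  The four default optima sit in distinct corners of the joint climate
  space with breadths of 1.5 degrees C and 18 mm (about 5% of each
  range). The corner placement is deliberate: mid-range climate
  combinations are the most common values on any smooth landscape, so
  mid-range optima manufacture background cells climatically identical
  to presences and cap achievable discrimination; peripheral optima
  give the cleanly separated niches the default scenario is meant to
  represent. With these defaults every model family reaches held-out
  AUC >= 0.9 and TSS >= 0.6, the regime reported for well-sampled
  montane endemics.
* **Occurrences** are drawn with replacement proportionally to true
  suitability and jittered within cells - deliberately clustered, so
  thinning has real work to do.
* **Trees** are pure-birth (Yule) chronograms rescaled to a root age
  of 11.3 Ma for four species, matching the depth of a
  Miocene-origin newt radiation; **traits** evolve by exact recursive
  BM simulation.

The generator does *not* emulate spatial autocorrelation of sampling
effort, topographic barriers, mass-elevation effects, niche asymmetry,
or observation error in coordinates. Passing tests therefore show the
pipeline's statistical machinery is correct under its own assumptions;
they do not show that a 1-km thinning radius or a 0.75 correlation cut
is right for any particular real system.

## Numerical choices

* Cell membership uses half-open intervals anchored at the lower-left
  corner; a point on an interior edge belongs to the higher-index
  cell. ESRI ASCII files are read north-up and stored south-up, with
  the mapping confined to the I/O layer.
* Thinning neighbourhoods use strict `< radius`, so a pair exactly at
  the radius co-exists.
* Haversine distances on a 6371-km sphere.
* PNO resampling returns bin midpoints by default, making point-mass
  profiles exactly reproducible; uniform-within-bin draws are a flag.
* The 80% central density is the equal-tail interval of the binned
  distribution with mass uniform within bins (the narrowest-interval
  estimator is available behind a flag).
* One user-facing seed; every stage, restart, repeat and permutation
  derives its own stream from it by hashing a short label, so stages
  can be re-run in isolation and whole runs are byte-reproducible.
* Boosting runs single-threaded; all model fits are deterministic
  given the seed.

## Problem sizes

The shipped tests run the full pipeline on the default 100 x 100-cell,
4-species scenario (and a reduced 30 x 30 variant for orchestration
tests), check the BM estimator against dense linear algebra on trees
of up to 12 tips, and measure root-state recovery on a 50-tip
chronogram over a few hundred simulation replicates - sizes chosen so
the whole suite completes in a couple of minutes on one core while
still leaving every code path exercised.

## Known limitations

Single-rate BM only (no Ornstein-Uhlenbeck, no rate shifts); no
projection to past or future climate scenarios; no MESS-style
extrapolation diagnostics; the MaxEnt surrogate does not reproduce
Phillips-style feature classes or regularisation paths; no formal
hypothesis test separates niche conservatism from divergence - the
tolerance table provides the per-node quantities and the labelling is
left to the analyst; and GeoTIFF input is not read - rasters travel as
ESRI ASCII grids.
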