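# ancniche

Climatic niche evolution for small clades: from occurrence records and
climate rasters, through ensemble niche models, to predicted niche
occupancy (PNO) profiles and maximum-likelihood reconstruction of
ancestral climatic tolerances on a dated phylogeny.

## Who this is for

Evolutionary ecologists and phylogeographers who have (a) presence
records for the species of a clade, (b) a stack of co-registered
bioclimatic rasters, and (c) an ultrametric chronogram with branch
lengths in millions of years, and who want to ask how the clade's
climatic tolerances evolved — the workflow behind studies of
phylogenetic niche conservatism and divergence in range-restricted
radiations such as montane newts or vipers.

## What it computes

- **Spatial thinning** of occurrences: retained points pairwise at
  least `r` km apart (default 1 km), maximal, haversine distances.
- **Pseudo-absences** equal in number to thinned presences, from
  background cells without presences.
- **Predictor pruning**: greedy elimination until no pair of climate
  layers has |Pearson r| > 0.75.
- **Four niche-model families** — GLM (linear + quadratic logistic),
  GAM (cubic-spline additive), GBM (gradient-boosted trees), and an
  L1-regularised MaxEnt-style surrogate — evaluated by repeated
  stratified splits with AUC, Cohen's kappa, and the true skill
  statistic `TSS = sensitivity + specificity − 1` at the max-TSS
  threshold, combined into a TSS-weighted consensus map, with
  permutation-based variable contributions.
- **PNO profiles**: each climate variable binned into 100
  equal-interval classes over the study extent; bin *k* holds the
  normalised sum of ensemble suitability of cells whose value falls in
  bin *k*. Overlap between species by Schoener's
  `D = 1 − ½ Σ|p_k − q_k|` and Hellinger-based `I = 1 − H²/2`.
- **Ancestral tolerances**: the chronogram is pruned to one terminal
  per species; tip values are resampled from the PNOs (100 draws) and
  Brownian-motion ancestral states are estimated for every draw by a
  linear-time pruning recursion
  (`root = (1'C⁻¹z)/(1'C⁻¹1)`, `σ² = Q/n`), giving per-node means,
  SDs and 80% intervals against node ages.
- **Synthetic study conditions** with known ground truth (smooth
  climate surfaces, Gaussian-niche species, clustered sampling,
  pure-birth chronograms, BM traits), so the whole pipeline is
  testable offline.

## Worked example

Generate the default synthetic bundle (four species on a 100 × 100
grid of six bioclim-style layers, a 4-tip chronogram with root age
11.3 Ma) and run the whole pipeline:

```r
library(ancniche)
cfg <- make_synthetic_bundle("demo", seed = 1)
run <- run_pipeline(cfg)
run
#> ancniche run: 10/10 stages complete, outputs in demo/out

head(run$results$models$evaluation, 8)
#>   species    model   AUC KAPPA   TSS
#> 1     sp1      GLM 0.954 0.880 0.880
#> 2     sp1      GAM 0.978 0.920 0.920
#> 3     sp1      GBM 0.978 0.920 0.920
#> 4     sp1 MAXENT_S 0.988 0.940 0.940
#> 5     sp2      GLM 0.974 0.891 0.891
#> 6     sp2      GAM 0.947 0.873 0.873
#> 7     sp2      GBM 0.946 0.891 0.891
#> 8     sp2 MAXENT_S 0.987 0.945 0.945
```

Every family discriminates presences from background with held-out
AUC well above 0.9 — the regime expected when niches are cleanly
separated in climate space. Niche overlap on the annual-mean
temperature analogue shows the two warm-adapted species (sp3, sp4)
sharing most of their profile and little overlap across the warm/cold
split:

```r
run$results$overlap$bio1$D
#>      sp1  sp2  sp3  sp4
#> sp1 1.00 0.71 0.49 0.45
#> sp2 0.71 1.00 0.57 0.53
#> sp3 0.49 0.57 1.00 0.89
#> sp4 0.45 0.53 0.89 1.00

subset(run$results$tolerance, variable == "bio1")
#>   node_id node_type age_ma variable mean   sd lower upper
#> 1     sp1       tip   0.00     bio1 10.4   NA  4.42  18.5
#> 2     sp2       tip   0.00     bio1 12.3   NA  7.09  18.5
#> 3     sp3       tip   0.00     bio1 17.2   NA  8.52  24.7
#> 4     sp4       tip   0.00     bio1 17.8   NA  9.07  24.8
#> 5       5  internal  11.30     bio1 15.1 3.14 10.75  18.5
#> 6       6  internal  10.06     bio1 14.6 3.11 10.88  18.1
#> 7       7  internal   4.07     bio1 15.3 3.32 10.75  19.3
```

The tolerance table is the tabular analogue of a
tolerance-through-time plot: tips at age 0 carry their PNO mean and
80% central density; internal nodes carry the across-sample mean of
the BM reconstruction at their age (the root, at 11.3 Ma, is
estimated near the middle of the extant species' tolerances, with the
warm and cold lineages diverging from it). `make_reports(run)` writes
these tables as TSVs, plus optional per-variable plots.

A thin CLI wrapper with `simulate`, `run` and `report` subcommands is
installed at `inst/scripts/ancniche.R`.

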