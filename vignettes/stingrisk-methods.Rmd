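---
title: "Methods: ensemble niche models and sting-risk vulnerability mapping"
author: "stingrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche models and sting-risk vulnerability mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Envenomation by scorpions and other venomous arthropods is a public-health
burden across arid regions, and the outcome of a sting depends on two
spatial quantities: whether dangerous species occur at a location
(*exposure*), and how far the victim is from medical care
(*accessibility*). Neither is directly observed wall-to-wall. `stingrisk`
estimates exposure from presence-only occurrence records with an ensemble
of ecological niche models (ENMs), and combines it with a
distance-to-nearest-city layer into a per-cell *vulnerability index*

$$V(x) \;=\; E(x)\,\times\, d(x),$$

where $E(x)$ is exposure at cell $x$ — a single species' binary habitat
prediction, or for multi-species maps either the species richness
$\sum_k B_k(x)$ (default) or the union $\max_k B_k(x)$ — and $d(x)$ is the
great-circle distance (km) from the cell centre to the nearest
healthcare-providing city. Richness is the default because overlapping
ranges of several dangerous species plausibly compound hazard; the union
variant is available and the definition used always travels in the map's
metadata.

## The modelling pipeline

For each species the pipeline is:

1. **Thinning.** Occurrences are thinned so no two retained points are
   closer than `min_dist_km` (default 1 km, matching a 30-arcsecond
   working grid). The algorithm is seeded greedy thinning: shuffle, then
   accept each point iff it is at least `min_dist_km` from every point
   already accepted. The result satisfies the distance constraint and is
   maximal (every removed point is within `min_dist_km` of a retained
   one); the shuffle seed is part of the run configuration.
2. **Pseudo-absences.** Presence-only data need a contrast class: 5000
   background points are drawn uniformly from distinct unmasked cells of
   the *ecoregions the species occupies*, excluding cells holding a
   presence, and jittered within their cell. Restricting the background to
   occupied ecoregions keeps the contrast within the region plausibly
   reachable by the species rather than trivially separable deserts-vs-
   mountains. Duplicated cells would add no information, hence sampling
   without replacement.
3. **Prevalence weighting.** Presences get weight 1 and each absence
   weight $n_p/n_a$, so the weighted prevalence
   $\sum w_i y_i / \sum w_i$ is exactly $1/2$ whatever the class ratio.
   Every ensemble member consumes these weights (weighted likelihood for
   GLM/GAM/Maxent, weighted boosting gradients, weighted bootstrap for the
   random forest).
4. **Collinearity screening.** Variance inflation factors,
   $\mathrm{VIF}_j = 1/(1-R^2_j)$ with $R^2_j$ from regressing predictor
   $j$ on the others, are computed on the training rows (the sample the
   models actually see; a full-raster mode would weight remote cells that
   never enter the fit). While any VIF $\ge$ 10, the worst predictor is
   dropped — ties keep the earlier-listed layer — and the report records
   the drop order and the final VIFs.
5. **Ensemble fitting.** Five members: weighted logistic GLM with linear
   and quadratic terms; weighted binomial GAM with per-layer thin-plate
   smooths; stochastic gradient-boosted trees (logistic loss, learning
   rate 0.1, depth 3, 100 rounds, subsample 0.7); probability random
   forest (500 trees) with the row weights as bootstrap case weights; and
   Maxent in its penalized-logistic form — an L1-penalized weighted
   logistic regression on linear, quadratic, pairwise-product and hinge
   features (10 quantile knots per layer, forward and reverse), with the
   penalty chosen by weighted deviance on an internal stratified 20%
   holdout. The ensemble prediction is the weighted mean of member
   probabilities; uniform weights by default, AUC-proportional weights as
   an option, and the choice is recorded in the map provenance.
6. **Evaluation.** 20 repetitions of a stratified 70/30 split (per class,
   `floor(0.7 n)` rows train, the rest test). Each repetition refits all
   members on the training part and scores the held-out part: weighted
   AUC (Mann–Whitney form, ties one half) and TSS = sensitivity +
   specificity − 1 at the held-out sensitivity-specificity-maximizing
   threshold. Stratification matters at small sample sizes (15-record
   species exist in real databases), where unstratified splits can produce
   single-class test sets. The reported TSS is the mean over repetitions
   of the per-repetition optimal-threshold TSS; this is one of several
   TSS conventions in use, and it is the one this package documents and
   tests.
7. **Binarization.** The published range map comes from members refit on
   the *full* table (the 20 splits serve evaluation only; refitting on
   all data maximizes the information in the final map while keeping
   evaluation honest). The threshold maximizes sensitivity + specificity
   over the ensemble scores at the training rows, computed once on the
   full-data scores rather than averaged over per-repetition thresholds;
   ties take the smallest threshold, and the threshold is stored in the
   map's attributes.

```{r example}
library(stingrisk)
land <- simulate_landscape(seed = 1)
vs <- virtual_species(land$env, list(intercept = 2,
  linear = c(env1 = 8, env2 = -8, env3 = 4),
  quadratic = c(env1 = -24, env2 = -24)))
occ <- thin_occurrences(sample_occurrences(vs, 300, seed = 1))
bg <- sample_background(land$ecoregions,
                        occupied_ecoregions(occ, land$ecoregions), occ,
                        seed = 1)
tab <- training_table(occ, bg, land$env)
fit <- enm(tab, seed = 1)
summary(fit)
bin <- binarize(fit, land$env)
dist <- distance_to_points(land$env$grid, land$cities)
vuln <- species_vulnerability(bin, dist)
```

## The synthetic study system

Real occurrence databases and 30-arcsecond climate surfaces are large,
licensed downloads; the package instead validates itself on a simulated
landscape with known truth. The generator's defaults are fixed study
conditions, not tuning knobs:

* **Grid.** 100 × 100 cells at 30 arcsec (≈ 0.93 km) over a southwest-
  Asian extent (52–52.83°E, 31.17–32°N) — the working resolution of
  1-km bioclimatic products.
* **Predictors.** Five standardized Gaussian-random-field layers
  (white noise convolved with a Gaussian kernel, range 5 cells, then
  mixed through the Cholesky square root of a target correlation matrix).
  Defaults impose correlation 0.6 between layers 1–2 and 0.4 between
  3–4, mimicking the moderate collinearity of real bioclim variables
  that survives a VIF < 10 screen. The achieved cross-correlation is
  within about 0.1 of the target on grids of 2500+ cells.
* **Ecoregions.** A Voronoi partition around six random seed cells —
  enough regions that occupied-region background sampling is a real
  constraint.
* **Virtual species.** True suitability is linear–quadratic logistic:
  $s = \mathrm{logis}(\beta_0 + \sum_j \beta_{1j} x_j + \beta_{2j}
  x_j^2)$ — expressive enough for the unimodal niches expected of
  thermophilous arthropods yet inside the model class of the GLM member.
  The *strong* reference niche used by the acceptance script is
  $\beta_0 = 2$, linear $(8, -8, 4, 0, 0)$, quadratic
  $(-24, -24, 0, 0, 0)$, truth threshold 0.5, occupying roughly 5–10% of
  the landscape. The sharp response and narrow range are what make the
  recovery target achievable: presences drawn $\propto s$ rarely fall in
  the logistic transition zone (a gradual response leaves many
  mid-suitability presences, which drag the max-sensitivity+specificity
  threshold down and inflate the predicted range), and suitable habitat
  overlaps little with a uniform background. A *flat* species ($\beta_0 = 0$,
  no responses) provides the no-skill null.
* **Sampling.** 300 presences (signal) or 200 (null) drawn with
  probability proportional to true suitability and jittered within their
  cell; optional Thomas-process clustering (off by default) mimics survey
  clumping. 25 cities at random unmasked cell centres.

What the simulation does *not* emulate: sampling bias correlated with
accessibility, positional error, species interactions, non-stationary
spatial autocorrelation, and real bioclim marginal distributions. Passing
the recovery checks therefore demonstrates the pipeline's correctness and
internal consistency, not that any real species' range is equally
recoverable.

## Numerical choices

* Distances are great-circle on a sphere of radius 6371 km on geographic
  grids, Euclidean in grid units on planar synthetic grids; the units
  travel in the layer metadata. Distance is measured from the cell centre
  to the city point, so a city-containing cell can carry a small nonzero
  value.
* Grids are cell-centre registered, row 1 = north, with half-open
  `[edge, edge + cellsize)` intervals on both axes, and every point→cell
  mapping goes through one function.
* Nodata is a mask, never a sentinel value in algebra; the mask of any
  result is the union of its operands' masks.
* AUC uses the tie-aware Mann–Whitney form; the max-sensitivity+
  specificity threshold scan includes a −∞ sentinel and resolves ties
  toward the smallest threshold, so degenerate all-suitable maps
  binarize to all-1 rather than erroring.
* All randomness flows from explicit seeds; per-stage seeds are derived
  from the master seed with a stated integer hash so any stage can be
  rerun in isolation. Generators restore the caller's RNG state.
* Rasters are written as ESRI ASCII grids with 17 significant digits
  (exact double round-trip) plus a JSON sidecar for the CRS tag; stacks
  as one grid per layer plus an ordered manifest.

## Problem sizes

Unit tests run on 10–50 cell grids with a few hundred training rows —
large enough to exercise every code path against brute-force oracles.
The end-to-end checks (no-skill null, signal recovery, pipeline
determinism) run at the full synthetic study scale: 100 × 100 cells,
300 (signal) or 200 (null) presences, 5000 pseudo-absences, all five
members, 20 evaluation splits, and five independent occurrence resamples
for the range-recovery median. These sizes were chosen as the smallest at
which the evaluation statistics are stable to within a few hundredths.

## Known limitations

* The five members are fixed algorithm families; no spatial-block
  cross-validation, response-curve analysis or variable importance.
* The distance layer treats access as straight-line distance; travel
  time along road networks would be more faithful where such data exist.
* The Maxent member is the penalized-logistic formulation; it shares the
  feature vocabulary of the classical implementation but not its exact
  default regularization path.
* Combined-exposure vulnerability is reported in exposure × km; an
  optional min–max rescale for cartography deliberately stays off so
  values remain interpretable.
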