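---
title: "Mapping BMI-class probability with stacked distribution models: methods and design"
author: "malnutMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping BMI-class probability with stacked distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malnutMap)
```

# The problem and the modelling frame

Nutritional surveys record where older adults live and their body-mass
index (BMI, kg/m^2), classified by the WHO cutoffs into underweight
(< 18.5), normal (18.5-24.9) and overweight-obese (> 25.0). The cutoffs
leave the sliver (24.9, 25.0] unassigned; `classifyBmi()` resolves it by
letting *normal* extend through 25.0, so overweight-obese is strictly
> 25.0. This is a convention, flagged here because any reimplementation
must pick one.

malnutMap treats each BMI class the way species distribution models
(SDMs) treat a species: the geo-located survey points of a class are
*presences*, the points of the other two classes are *absences*, and the
environment is a stack of gridded covariates on 1-ha (100 m) cells —
distances to the city center, roads and food amenities, road and
building densities over 100-1000 m neighborhoods, an NDVI-style
greenness field with five moving-window texture statistics, elevation
and slope, population and nightlights layers. The product is, per class
and city, a probability surface over the older-adults mask, an
uncertainty (standard deviation) surface, and a two-tier hotspot map.

# The synthetic landscape: what it emulates, and what it does not

Household-level nutritional surveys are not redistributable, so the
package carries a seeded generator (`landscapeConfig()`,
`generateCovariates()`, `simulateSurvey()`) that emulates the study
setting with known ground truth:

* **Covariates.** Random fields are Gaussian-smoothed white noise with
  kernel width `spatialRange / cellSize`; the default `spatialRange` of
  500 m produces neighborhood-scale patchiness typical of resampled
  remote-sensing products. Distance and density layers are computed
  from a synthetic road network (radial spokes from the city center
  plus a 500 m street grid in the urban quadrant) and clustered amenity
  points, so urban-rural contrast is real, not painted on.
* **Outcome model.** Per-cell class probabilities follow a 3-class
  multinomial logit on standardized covariates (reference class
  *normal*). The default effects make overweight-obese more likely
  with denser roads (+1.5 per SD) and nearer the city center (-1.0 per
  SD of distance), and keep underweight rare (base rate 10%),
  reproducing the class-imbalance regime of urban aging surveys in
  which very few underweight older adults are found.
* **Points.** At most one point per cell, only inside the
  built-up/older-adults mask (the top 35% of an urban-plus-noise
  score). Classes are drawn from the per-cell multinomial and steered
  to the per-class quotas by rejection, with a capped budget and a
  probability-weighted fallback, so configured counts are met without
  biasing the spatial pattern.

The generator's defaults were fixed once — 60 x 60 cells at 100 m,
quotas (50, 250, 250) — as a desk-scale stand-in for a city of a few
thousand hectares. What it does **not** emulate: sensor artifacts
(radiometric drift, SRTM voids), GPS error, the four-strata *barangay*
sampling design (only its spatial clustering is mimicked), and
day-to-day survey logistics. Green tests on this landscape therefore
demonstrate algorithmic correctness and statistical behavior under a
known generative model, not performance on any real survey.

# Sampling design: backgrounds and the area of applicability

Presence-only learners need background (pseudo-absence) samples.
Because surveys oversample accessible neighborhoods, a uniform
background would let the models learn the survey bias instead of the
environment. `sampleBackground()` therefore draws *target-group*
background: cells sampled with weight proportional to a Gaussian
kernel-density surface of the presences (Scott's-rule bandwidth per
coordinate), restricted to the older-adults mask, excluding every cell
already holding a survey point. The default background size is 10x the
presence count, capped by the eligible cells.

`dissimilarityIndex()` delimits the *area of applicability* (AOA): for
each cell, the distance in standardized, importance-weighted covariate
space to the nearest training point, normalized by the mean pairwise
distance among training points. The support threshold is the upper
whisker (Q3 + 1.5 IQR) of the training points' own leave-one-out DI —
so by construction at least three quarters of the training data are
self-supported. Cells beyond the threshold are under-sampled: they are
excluded from background sampling and from tier-1 hotspots.
Zero-variance covariates are excluded from the DI with a warning;
all-identical training sets are an error.

# The learners

Five base learners sit behind one train/predict contract
(`learnerSpec()`, `tuneLearner()`, `fitMaxent()`,
`fitPresenceAbsence()`):

* **maxent_lq, maxent_lqh** — MaxEnt-style presence-background models,
  implemented as L1-penalized logistic regression on expanded feature
  classes (the maxnet formulation): linear + quadratic terms for
  `lq`, plus forward/reverse hinge features at the 25/50/75% quantile
  knots for `lqh`. The penalty weight lambda is the tuned
  hyperparameter; as lambda grows the model degenerates gracefully to
  the constant presence fraction, so complete separation cannot
  diverge. The two variants differ only in feature class, a natural
  reading of "two MaxEnt models".
* **random_forest, boosted_trees, neural_net** — presence-absence
  classifiers (randomForest; xgboost with `binary:logistic`; a
  single-hidden-layer nnet with tuned width and weight decay,
  standardized inputs).

Tuning is an exhaustive grid search by k-fold (default 5) mean held-out
AUC. Grids are deliberately small (at most 8 combinations per family)
and configurable; ties break toward the least complex setting (strongest
penalty, fewest trees), reflecting the overfitting concerns that
motivate stacking in the first place. Every stochastic fit derives its
stream from the spec seed, so identical inputs give identical models.

# Stacked generalization

`fitStack()` shares one fold assignment (stratified by row role) across
all five base learners, then assembles the *out-of-fold* base
predictions at the presence and absence rows into the meta-design: a
base model contributes a prediction for a row only if that row was
outside its training fold, so the meta-learner never sees leaked
information. For absence rows — which the presence-background learners
never train on — the prediction comes from the model of the row's own
fold.

The meta-learner is a random forest on the five prediction columns. It
receives the same treatment as every other model: a small grid over
forest mode (probability forest vs regression on the 0/1 label),
`mtry` and `nodesize` is evaluated by the shared-fold mean CV AUC and
the winner is kept, with the full grid retained in `metaGridLog`. This
matters in the regime where one base learner dominates: an untuned
meta forest overfits the weaker prediction columns and can trail the
best base learner, whereas generous leaf sizes let the forest act as a
smooth, nearly monotone combiner. Ensemble CV metrics are computed by
refitting the winning meta per fold and scoring held-out folds
(threshold-maximized TSS per fold, as is standard in the SDM
literature; the paper-style dichotomization threshold is not fixed a
priori and is logged per fold).

`predictSurface()` evaluates base finals and the meta final over masked
cells in chunks (default 5000 cells) so memory stays bounded; the
uncertainty layer is the per-cell standard deviation of the five base
probabilities, and per-cell class probabilities of different classes
are deliberately *not* renormalized to sum to 1 — each class surface is
an independent model, as in the mapping workflow this package follows.

# Interpretation

* **Decorrelation** (`decorrelate()`): covariate pairs with |Pearson r|
  > 0.8 are resolved iteratively, largest |r| first; the member whose
  leave-one-variable-out refit loses more CV AUC (the variable the
  model is more sensitive to) is kept. The order of resolution is a
  design choice — the procedure is greedy — and every decision is
  logged. Constant variables are dropped first with a warning.
* **Jack-knife importance** (`jackknifeImportance()`): one
  single-variable model per roster variable; its mean CV AUC (displayed
  x 100) is the importance. Failed fits are recorded as 0.5 and
  flagged.
* **Permutation importance** (`permutationImportance()`): per iteration
  (default 10) and variable, the column is shuffled and the AUC drop
  recorded; negative drops are clipped to 0 (relative contributions
  live on 0-100%), contributions are normalized to 100% per iteration
  and averaged. An all-zero iteration returns uniform shares with a
  warning.
* **Category aggregation** (`aggregateByCategory()`): jack-knife AUCs
  average within a category (an AUC is not additive); permutation
  shares sum and renormalize. Cross-city consistency
  (`crossCityConsistency()`) is the mean absolute Pearson correlation
  of category-importance vectors over city pairs.
* **Response curves** (`responseCurve()`): partial dependence — one
  variable swept over its observed range with all other columns at
  their actual values, averaged, per CV fold, reported as a mean curve
  with a min-max fold band.

# Hotspots

`delineateHotspots()` applies a strict `> 0.8` probability cutoff
(Hotspot 2) and intersects it with the AOA (Hotspot 1), so tier 1 is
always nested in tier 2 and raising the threshold can only shrink a
hotspot; NoData never counts. `summarizeByUnit()` assigns cells to
administrative polygons by the cell-center rule (boundary ties go to
the first polygon in list order, logged by position) and reports areas
in hectares from the grid's actual cell size (1 cell = 1 ha only at
100 m), sorted by tier-1 area as a priority ranking; cells covered by
no polygon appear as `unassigned`.

# Numerical and scale choices

* AUC is rank-based (Mann-Whitney, ties counted one half), identical to
  trapezoidal ROC integration and invariant under monotone transforms;
  an integer-overflow-safe implementation handles 10^5-point inputs.
* TSS requires all four confusion-matrix margins non-empty; the
  threshold maximizing TSS is scanned over the observed scores.
* Cross-validation folds are random and stratified on the label;
  splits degenerate folds are retried, and at k = n (leave-one-out)
  metrics pool the out-of-fold predictions since single-row folds have
  no AUC.
* Rasters are matrix-backed S4 objects with an explicit
  `GridGeometry` (upper-left origin, row-major, cell-center
  convention); I/O uses plain-text formats — Esri ASCII grids for
  rasters, GeoJSON for vector layers, CSV for points, YAML for
  configuration — chosen so every artifact is diffable and
  platform-neutral.
* Distances are planar Euclidean on the projected grid (as in the
  proximity products the covariates emulate), and density layers use
  analytic segment-circle clipping rather than rasterized
  approximations.
* Default problem sizes (60 x 60 landscape; 100 x 100 for the
  reference benchmark with 200 presence / 200 absence / 2000
  background) were chosen once as desk-scale analyses a laptop
  completes in minutes.

# Known limitations

* Random (not spatially blocked) cross-validation is used by design;
  with strongly autocorrelated covariates it can flatter all models
  alike. Spatial blocking is out of scope.
* The AOA threshold follows the whisker rule of its source method; no
  attempt is made to calibrate it against prediction error.
* Greedy pairwise decorrelation does not guarantee a globally optimal
  roster, only the |r| <= 0.8 post-condition.
* The synthetic landscape's drivers are known and additive on the
  logit scale; real surveys face interactions, measurement error and
  confounding that no test here exercises.
* Hotspot delineation is pure thresholding; no minimum-patch-size
  filter or local spatial statistics are applied.

# A worked run

```{r, eval = FALSE}
cfg <- pipelineConfig(
  landscape = landscapeConfig(gridShape = c(40L, 40L), seed = 1L),
  classes = "overweight_obese", city = "demo",
  outdir = "demo_run")
man <- runPipeline(cfg)
man$results$demo_overweight_obese$metrics
```

The manifest records stage status, parameters and every written
artifact; rerunning with `resume = TRUE` reuses cached stages and
reproduces identical outputs under the same seed.
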