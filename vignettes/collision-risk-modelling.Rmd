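---
title: "Modelling bird collision risk at wind turbines from carcass searches and distance-to-edge landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bird collision risk at wind turbines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`collrisk` estimates where a wide-ranging raptor is likely to collide with
wind turbines, and where those collisions would matter most for the
population. This vignette is the package's account of the science: the
model and its assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic study system does and does not
emulate, and the numerical decisions a reader should know before trusting a
number.

## 1. The inference problem

Carcass searches beneath turbines provide an opportunistic presence signal:
a turbine where a target-species carcass was found is a *presence*, a
searched turbine where only other bird groups were found is a
*pseudo-absence*. Turbines with finds of other raptors in the target's own
family are excluded — they are neither evidence of the target's presence
nor credible absences, since family-mates use similar habitat. Turbines
never searched carry no information and are dropped. Counts of individuals
per find are deliberately ignored: the sampling unit is the turbine, and
repeat finds say more about search effort than about the landscape.

The predictors are *distance-to-edge land-use variables* (DELVs): for each
of 12 land-use classes, the signed Euclidean distance from a location to
the class's nearest edge, negative inside the class. Distances to edges —
rather than membership or cover fractions — matter because perching,
hunting and display behaviour of buzzard-like raptors concentrates along
habitat boundaries.

## 2. Distance engine

All rasters live on one planar grid of 100 m square cells. For each class:

1. **Edge cells** — cells whose square is crossed by the class boundary
   polyline. A boundary segment lying exactly on the line between two cells
   is attributed to the cell on the polygon's interior side (implemented by
   nudging the segment one micrometre inward). This makes a polygon tracing
   a single cell's outline mark exactly that cell, and keeps the edge set a
   subset of the class itself. Rings are assumed oriented in the usual way
   (exteriors counter-clockwise, holes clockwise).
2. **Inside cells** — cell centres inside the even-odd union of the class's
   rings. A centre exactly on a boundary counts as inside; the tie needs a
   deterministic rule, and such cells are edge cells (distance 0) anyway.
3. **Signed distance** — an exact Euclidean distance transform (two-pass
   lower-envelope algorithm, computed in C++) from the edge-cell set,
   centre to centre, multiplied by the cell size and negated inside.

Distances are computed on the rasterized edge set, not against exact vector
geometry. At 100 m resolution the difference is below the cell scale, and
the raster formulation admits an exact brute-force oracle (the test suite
compares 100 random masks against an all-pairs scan at 1e-9 m). Point
sampling uses the containing cell (nearest-cell rule); whether the original
workflow interpolated is unknowable from the outside, and nearest-cell is
the only choice consistent with "the value of the grid cell".

## 3. Boosted regression trees

The response is Bernoulli with logit link — the natural choice for a binary
presence/pseudo-absence response. The ensemble is classical stagewise
boosting: the intercept is the empirical log-odds; each iteration draws a
`bf` fraction of rows without replacement, fits a regression tree with at
most `tc` splits to the current gradient `y - p` (best-first, by
squared-error improvement), and appends it scaled by `lr`. Terminal values
are Newton steps `sum(y - p) / sum(p(1-p))` on the in-node rows.

Defaults: `tc = 12` (the number of predictors, allowing interactions up to
that order), `bf = 0.5`, `min_node = 10`. With `bf = 1` the training
deviance is non-increasing by construction, and the test suite asserts this
exactly over 500 trees.

**Tree-number selection.** `brt_step()` fixes stratified 10-fold CV
partitions once per call, grows all folds in parallel, and records the
held-out deviance after every tree; `nt` is the arg-min of the mean CV
deviance on a 50-tree step grid. Growth stops when the running arg-min
trails the frontier by at least four steps, or at `max_trees`. The
learning-rate ladder 0.05, 0.01, 0.005, 0.001, 0.0005 is descended until
the selected `nt` reaches 1000 trees — the usual calibration goal for
ecological BRTs, trading many small steps for stability — and the last rate
is returned with a warning if none does. Recording deviance per tree rather
than only at step boundaries costs nothing and makes the curve available
for inspection; `nt` itself stays on the step grid.

**Interpretation.**

* *Relative influence*: per-variable sums of split improvements over the
  ensemble, normalised to percentages. Exact improvement ties between
  variables are broken alphabetically by name, not by column position, so
  fits are invariant under reordering of the feature columns (a property
  the suite checks bit-for-bit).
* *Partial dependence*: mean link-scale prediction over the training rows
  with one variable overwritten, evaluated on 100 equally spaced quantiles
  of that variable's training values.
* *Interaction size*: on a `grid_size x grid_size` quantile lattice for a
  variable pair, the two-way partial-dependence surface is fitted by the
  best additive (row effect + column effect) least-squares model — on a
  complete balanced lattice that fit is exactly the row/column means — and
  the interaction size is 1000 x the mean squared residual. The statistic
  is zero for additive pairs and symmetric by construction. Its *scale* is
  a package convention chosen to land small interactions near zero and
  substantial ones around order one; published interaction sizes from other
  implementations are comparable only qualitatively (by ranking), not
  numerically.
* *Simplification*: drop the currently least influential variable, refit
  with the full stepped protocol, repeat up to `max_drop` times (default
  workflow: drop 2 of 12, refit on 10). Tree complexity is left at its
  configured value rather than re-tied to the shrinking predictor count;
  with 10+ predictors the distinction is immaterial because `tc` bounds,
  not prescribes, the splits per tree.

**Evaluation.** AUC is the rank statistic (ties count half), checked in the
tests against an all-pairs oracle and against an independent ROC
implementation. The classification threshold defaults to the Youden rule
(maximising sensitivity + specificity − 1) because published
sensitivity/1−specificity pairs in this field rarely state their threshold;
a fixed threshold can be supplied instead. Cross-validated deviance
explained is `100 (null − CV) / null` with a fold-wise standard error.

## 4. Risk overlay

Breeding-pair density atlases report classes on a map-sheet quadrant
tiling; the six classes have lower borders 1, 2, 4, 8, 21, 51 pairs.
Analyses use the lower border (a conservative density figure), normalised
by the maximum lower border 51:

SC = CP × (BPDobs / 51) × 100.

SC is in [0, 100] and equals 100 only where the collision potential is 1
*and* the density class is the highest. Cells outside every density
quadrant get BPDrel = 0: no recorded breeding pairs, no susceptibility.
Zones are [0,20], (20,40], (40,60], (60,80], (80,100] — half-open below so
the bins are exhaustive and disjoint; a value of exactly 20 is zone 1.
Zone-table percentages are *truncated* (not rounded) to two decimals; that
convention reproduces published zone tables of this kind, and where a
printed percentage disagrees with its own counts under every rounding rule
the package reports its own arithmetic.

Kernel density surfaces for turbine and collision locations use a Gaussian
kernel normalised discretely on the grid, so the surface integrates to the
point count (exactly, for points away from the boundary; the suite checks
1% on interior points).

## 5. The synthetic study system

No carcass, turbine or biotope data are redistributable here, so the
package generates its own study region with known ground truth. The
generator *is* the study condition for every stochastic test.

**Landscape.** Seeded multi-source region growing on the 100 m grid: each
class gets seed cells and a cell quota proportional to its target coverage;
the class with the largest relative remaining quota grows one cell at a
time from a randomised frontier; a class whose patch gets enclosed is
replanted at a random free cell. This guarantees a partition (the biotope
semantics: every cell belongs to exactly one class) with realised coverages
matching the targets. Default coverages are the state-wide fractions of the
twelve classes (fields 35.1%, forests 35.5%, grasslands 16.4%, down to
ruderal areas at 0.26%). Dominant classes (≥5% coverage) form 1500 m
patches; rare classes form 500 m patches with at least four per class,
because watercourses, bush groups and village greens occur as many small
dispersed features in real biotope maps, and a single blob would
misrepresent the distance distributions the model feeds on. The per-class
cell sets are polygonised by boundary tracing (interior kept left; left
turns at saddle vertices keep diagonal patches in separate rings) and
round-trip exactly through GeoJSON.

**Risk model.** The generative collision model is logistic with an
intercept of +0.5 log-odds and four piecewise-linear distance drivers,
mirroring the qualitative risk pattern the package is designed to detect —
risk elevated far from flowing watercourses (>1000 m), far from grassland
edges (>750 m), inside a 750–1750 m band around green areas near
settlements, and far from bushland edges (>1500 m). Each driver is a
smooth step: a log-odds deficit of 2.5–4.5 near the class edge vanishing
beyond the stated threshold (the band driver is a surplus of 4 inside the
band). Amplitudes were fixed once so that the generative model's own
discrimination is comparable to a well-performing field model (held-out AUC
in the mid-0.8s), making the recovery experiments informative: a fitted
model that matches the generator's AUC has extracted essentially all the
signal there is.

**What is deliberately not emulated.** Carcass persistence, scavenger
removal and searcher efficiency — the known biases of carcass-search data —
are not simulated, because no quantitative bias structure is available to
copy; passing recovery tests therefore says nothing about robustness to
detection bias in real data. Likewise absent: temporal dynamics, spatial
autocorrelation between classes (water near wetlands, settlements near
green areas), truly linear stream networks (approximated by dispersed small
patches), and heterogeneous search effort (monitoring covariates are
carried through the tables but never used as predictors, matching the
modelling protocol).

## 6. Reproducibility and problem sizes

Every stochastic stage draws from a stream derived from one global seed by
fixed offsets, so stages are independently reproducible and the end-to-end
pipeline is byte-identical across runs with the same configuration — the
suite asserts this on the zone-count table and the collision-potential
raster. C++ code uses its own seeded generator (no R RNG state leaks).

The shipped experiments run at desk scale, chosen so the full suite and the
acceptance script each finish in minutes on one CPU: 15 km × 15 km
landscapes (150 × 150 cells) with 1500 simulated turbine points and
balanced 400-row training sets for the recovery study; 8 km regions for
pipeline round-trips; 40 × 40 masks for the distance oracle. The modelling
protocol itself has no scale-specific shortcuts; larger regions only cost
time.

## 7. Known limitations

* Pseudo-absences are *searched turbines without target finds*, not
  verified absences; the fitted probabilities are detection-conditional and
  should be read as relative, not absolute, collision rates.
* The flowing-watercourse driver is the hardest to recover: it is active on
  the smallest fraction of the landscape, and in a minority of replicates a
  correlated rare class (still watercourses) takes its influence rank.
  That is a property of the inference problem, not a bug — with few
  informative points, influence ranks are noisy.
* The interaction statistic's scale is a package convention (see §3); only
  rankings are transferable.
* GeoTIFF is not written; rasters use the plain-text ESRI ASCII grid, which
  any GIS reads, to keep the toolchain dependency-free.
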