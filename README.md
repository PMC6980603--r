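# collrisk

Collision-potential and strike-susceptibility modelling for soaring birds at
wind turbines.

Carcass searches beneath wind turbines yield presence/pseudo-absence data on
collision victims. `collrisk` turns such data, together with a land-use map,
into (i) a spatial model of **collision potential** — the probability that a
turbine location produces a collision detection — and (ii) a
**strike-susceptibility** map that weights that potential by the regional
breeding density of the species, the quantity a planner actually needs when
siting new turbines. The package is aimed at spatial ecologists and
conservation planners working on wildlife–wind-energy conflicts, and ships a
fully synthetic study system (landscape, turbines, collisions, density
atlas) with known ground truth so every stage can be exercised and validated
without field data.

## The model

**Predictors.** Each of 12 major land-use classes (fields, forests,
grasslands, flowing/still watercourses, bushlands, settlements, …) is
reduced to a *distance-to-edge land-use variable* (DELV): the signed
Euclidean distance (metres, on a 100 m grid) from a location to the nearest
edge of that class — negative inside the class, positive outside.

**Response model.** Boosted regression trees (BRT) with Bernoulli loss and
logit link, built from scratch: forward-stagewise ensembles of shallow
regression trees fit to the loss gradient,

> f(x) = β₀ + lr · Σₜ Tₜ(x),

with tree complexity *tc* (splits per tree, default 12), learning rate *lr*
(scanned over 0.05…0.0005), bag fraction *bf* = 0.5, and the ensemble size
*nt* chosen by stepped 10-fold cross-validation on predicted deviance,
descending the learning-rate ladder until at least 1000 trees are fitted.
Interpretation follows standard BRT practice: relative influence from
squared split improvements, partial-dependence curves, pairwise interaction
sizes from the residual of an additive fit to the two-way
partial-dependence surface, and simplification by sequentially dropping the
least influential predictors.

**Overlay.** With `BPDobs` the lower border of the local breeding-pair
density class (six classes: 1, 2–3, 4–7, 8–20, 21–50, 51–150 pairs) and
`BPDmax = 51`:

> BPDrel = BPDobs / BPDmax,  SC = CP × BPDrel × 100,

giving a 0–100 strike-susceptibility index, binned into five 20-point zones
for turbine counting.

## Worked example

One replicate of the synthetic study: generate a 15 km landscape, simulate
collisions under the default four-driver risk model, fit the stepped BRT on
a balanced 400-row training set, and evaluate on a 30% stratified hold-out:

```r
library(collrisk)
rep1 <- recovery_replicate(seed = 1)
rep1$model
#> brt_model: 3150 trees (nt = 3150), lr = 0.001, tc = 12, 12 predictors
#>   CV: 10-fold, mean predicted deviance 1.0517 at nt = 3150
head(rep1$influence, 5)
#>   variable influence
#> 1       GS 19.463797
#> 2        B 14.678646
#> 3       GF 11.391581
#> 4       SW 10.222381
#> 5       FW  8.426565
rep1$eval
#> AUC 0.848 (sensitivity 0.72, 1-specificity 0.12 at threshold 0.554)
#> CV deviance explained: 24.1% (SE 3.38)
```

The learning-rate ladder stopped at 0.001, the first rate whose
cross-validated optimum exceeds 1000 trees. Three of the four generative
drivers (GS: green areas around settlements, B: bushlands, GF: grasslands)
top the influence ranking, with flowing watercourses (FW) fifth in this
replicate; the held-out AUC of 0.85 sits close to the generative model's
own discrimination, i.e. most of the recoverable signal is recovered.

The full pipeline — landscape → distance rasters → training set → model →
collision-potential raster → susceptibility zones → per-status turbine
counts — runs from one config:

```r
man <- run_pipeline(pipeline_config(seed = 1), "run1")
man$metrics$zones
```

or from a shell via the launcher in `inst/scripts/collrisk.R`
(`run-all`, `simulate`, `delv`, `train`, `predict`, `susceptibility`,
`report`; `--config cfg.yaml --seed 1 --out run1`). Outputs are GeoJSON
(vector layers, density map), ESRI ASCII grids (all rasters), CSV (turbine,
training and zone-count tables) and JSON (models, evaluation, manifest with
file hashes).

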