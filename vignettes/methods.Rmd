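---
title: "Modelling mountaintop habitat under climate change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mountaintop habitat under climate change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Alpine specialists live on "sky islands": disjoint patches of habitat above
the treeline. A warming climate pushes their climatic envelope uphill, and
because mountains narrow toward their summits, the same uplift that merely
*shifts* a lowland species' range *shrinks and fragments* an alpine one.
`skyisland` quantifies that process: from a digital elevation model, climate
surfaces and point sightings it derives predictors, builds a constrained
pseudo-absence background, fits and thresholds an ensemble classifier,
projects suitability across a factorial of climate scenarios, and reports
habitat amount and configuration (range change, patch number, size and
elevation) per scenario.

This vignette documents the model, its assumptions, the tunable parameters,
the synthetic data generator, and the numerical and design choices — in the
order the pipeline runs them.

## Terrain predictors

* **Slope / aspect** use Horn's 3×3 finite differences with double-weighted
  cardinal neighbours. Cells without a complete 3×3 valid window (the grid
  border and the nodata margin) are nodata; zero-gradient cells get slope 0
  and an *undefined* aspect. Aspect is degrees clockwise from north, the
  downslope direction.
* **Aspect transform**: `x = -cos(aspect * pi/180)`, −1 on north-facing and
  +1 on south-facing slopes, a proxy for solar incidence. Aspect carries no
  information on near-level ground, so cells with slope < 5° (and flats)
  are set to the neutral value 0. The 5° cutoff is exposed as
  `flat_slope`.
* **Flow accumulation** is D8: each cell drains to the steepest-descent
  neighbour of eight, with drop divided by distance (diagonals √2 longer).
  Depressions are filled first by priority flood: a min-heap sweep inward
  from the boundary that raises every internally drained cell to its spill
  level **plus a tiny epsilon per step** (default 10⁻⁴ m), which gives
  filled flats a deterministic gradient toward their spill point. We chose
  the epsilon-increment variant over explicit breadth-first flat assignment
  because it produces the same deterministic drainage with one pass and no
  special flat-region handling. Steepest-descent ties break by the fixed
  neighbour order N, NE, E, SE, S, SW, W, NW. Cells with no lower valid
  neighbour are outlets. `fill = FALSE` exposes raw-surface routing for
  studying sinks.
* **CTI** = ln(As / tan β), As = (accumulation + 1) × cell area in m²,
  β = slope in radians floored at `beta_min = 0.001` rad so level cells
  keep a finite index (the common GIS convention).
* **VRM** sums unit surface normals (sin s sin a, sin s cos a, cos s) over
  the 3×3 window and reports 1 − |resultant|/n. Flat cells contribute a
  vertical normal; n counts the valid cells actually present, so cells at
  the edge of the valid region use the neighbours they have.

Conventions throughout: row 1 is the north edge, cell centres sit at
half-cell offsets, coordinates are metres in a projected system, cells are
100 m squares by default.

## Occurrence filtering

The cleaning cascade runs in a fixed order: summer window (months 6–10,
inclusive of both endpoints), juvenile removal, exact-coordinate
deduplication, then for marked individuals a *chronological greedy sweep*
that keeps a record only if it falls at least one day after the last kept
record, and finally a random cap of at most two records per individual.
The sweep direction (earliest first) is a documented choice — the rule
itself doesn't dictate one — and is seed-independent; only the per-
individual cap and the grid-thinning draw consume randomness. Individuals
with fewer than two remaining records keep them all. Public records are
instead screened by stated coordinate accuracy (≤ 100 m, boundary
inclusive) and deduplicated. Both sources are thinned to one random record
per 100 m grid cell before merging; shared cells in the merged set are
resolved by one more random draw. Every step appends its removal count to
a filtering report carried on the tibble.

## Background and pseudo-absences

True absences are unavailable for rare, patchily surveyed species, so the
model contrasts presences with *pseudo-absences* drawn from the landscape
the species plausibly encounters: cells whose centres lie inside the
minimum convex polygon of all presences dilated outward by 200 m (the
polygon bounds the surveyed range; the buffer is outward only), restricted
to the subalpine and alpine zones (discriminating "suitable" from "highly
suitable" ground rather than contrasting mountaintops with sea level), and
excluding a **closed** 200 m ball around every presence (within a typical
daily movement radius, a cell cannot be confidently called unused; a centre
at exactly 200 m is excluded). Eligibility is decided at cell centres —
exact and resolution-consistent at 100 m. Pseudo-absences are sampled
uniformly without replacement at 2 per presence; the 1:2 ratio follows the
sensitivity exploration convention for this design.

## Model, threshold, metrics

The classifier is a 1500-tree classification random forest with
mtry = ⌊√8⌋ = 2, fitted via the `randomForest` package; the package's
contribution is the pipeline around it, and any bagged ensemble exposing
out-of-bag votes and importances could stand in. All evaluation uses
out-of-bag (OOB) probabilities: row i is scored only by trees whose
bootstrap excluded i.

The suitability threshold implements "maximize sensitivity at 0.90" as:
scan every candidate cutoff (the unique OOB probabilities plus 0 and 1) and
take the **largest** cutoff with sensitivity ≥ 0.90 — the most conservative
binarization that still classifies 90 % of presences correctly. For a
threatened species, omission errors (missing real habitat) are costlier
than commission errors, so mild over-prediction is accepted by design.
Cells *at* the threshold count as suitable, consistent with that stance.
Reported metrics: sensitivity, specificity, Cohen's kappa (chance agreement
from the marginals), TSS = sensitivity + specificity − 1, and a rank-based
(Mann–Whitney) AUC, which is threshold-free and invariant under monotone
transforms of the scores.

## Scenarios and projection

A scenario is (GCM, RCP, period) with an additive temperature offset
`d_mst` (°C) and multiplicative precipitation and snowfall factors
(`d_msp`, `d_pas`) applied to the baseline climate surfaces. The default
table spans +0.8 °C (CCSM, RCP 4.5, 2025) to +5.0 °C (Can, RCP 8.5, 2085),
ordered Can > GFDL > CCSM and 8.5 > 4.5, with the wettest model gaining the
most precipitation. `d_pas` stays at 1 in the defaults: snowfall already
declines with temperature through the generator's snow-fraction coupling,
and an exogenous multiplier on top would double-count that mechanism.
Snowfall still falls under every warming scenario. These magnitudes are
configuration, not data; `validate_scenario_table()` enforces baseline
identity and within-scenario monotone warming.

Projection applies the forest per cell (vote fraction), propagates nodata,
binarizes at the chosen threshold, and requires the full factorial
(1 + 3×2×3 = 19 maps), naming any missing combination. GCM-ensemble maps
average the three GCMs' *probability* surfaces before thresholding
(averaging the binary maps instead is available through per-map access);
mean-probability is the default because thresholding is the last lossy
step.

## Configuration metrics

Habitat area is suitable cells × 0.01 km². Range change is
RC = 100 × (RG − RL)/BR summed cell by cell. Patches are connected
components under queen (8-neighbour) adjacency by default — at 100 m
resolution, mountain ridgelines connect diagonally — with rook (4)
available. No minimum patch size is applied. Patch elevation is reported
two ways: `mean_patch_elevation_m` weights every patch equally (each
patch's mean cell elevation, then mean and SD across patches), matching a
per-patch error-bar presentation; `habitat_elevation()` weights every cell
equally and is the more stable statistic when fragmentation produces many
small patches. Cross-GCM summaries report mean ± SE (SD/√3) per
RCP × period, and mean ± SD for elevation.

## The synthetic landscape

The generator produces the statistical structure the analysis assumes,
not a portrait of any real place:

* **DEM**: a north–south spine of six summits with graded heights (0.58 to
  0.95 × `ridge_height`, highest mid-island), Gaussian shoulders with
  per-seed jittered positions and widths, plus smooth correlated noise
  (separable Gaussian kernel, correlation length 6 cells), clamped to
  [0, `ridge_height` = 2200 m], with an ocean ring of nodata. The
  multi-summit hypsometry is deliberate: area declines *gradually* with
  elevation, so a warming-driven uplift of the habitat band removes area
  summit by summit — single-ridge islands lose their habitat in one step
  and produce degenerate scenario responses.
* **Climate**: mst = 18 °C − 6 °C/km × elevation + smooth noise
  (sd 0.8 °C); the noise sd is large enough to decouple temperature from
  elevation locally (topoclimate), which is what lets a correlative model
  attribute suitability to climate rather than elevation alone. msp grows
  westward (15 mm/km) and with elevation (0.2 mm/m) from a 400 mm base;
  pas = 6 × msp × plogis(−0.15 × mst): snowfall rises with precipitation
  and collapses as summers warm.
* **Zones**: elevation bands at 750 m and 1350 m stand in for the coastal
  forest / subalpine / alpine zonation (temperature-space banding available
  when an mst surface is supplied).
* **Occurrences**: presence cells are drawn with probability ∝
  plogis(−12 + 1·z(elev) − 3·z(mst) + 1.5·z(pas) + 0.3·z(aspect_t))
  (z = standardized over valid cells), mostly within the subalpine/alpine
  zones. The strongly negative intercept keeps the suitability surface
  from saturating over the alpine zone — a saturated truth makes presences
  indistinguishable from the zone-constrained background — and the
  climate-heavy weights encode a thermally/snow-limited specialist. Records
  are then dressed as raw data: field individuals with home ranges, repeat
  sightings < 1 day apart, ~15 % juveniles, exact-coordinate flock
  duplicates, ~15 % off-season dates; public records with mixed accuracy
  (~25 % coarser than 100 m). Defaults of 207 field + 137 public records
  match a realistic raw fixture at small landscape sizes; `run_pipeline()`
  draws 530 + 340 by default so that *after* the cascade the modelling set
  lands near the canonical ~330 presences + 2× pseudo-absences.

What the generator does **not** emulate: real geography and drainage
networks, observer effort gradients and spatial reporting bias, coordinate
error in the simulated positions themselves, interannual climate
variability, and downscaled scenario surfaces (offsets are spatially
uniform). Passing tests therefore demonstrate that the pipeline's logic is
correct and that the method recovers a known truth under its own
assumptions — not that any particular real-world projection is right.

## Numerical choices and degenerate inputs

Tie-breaks and boundaries are all deterministic and documented: fixed
neighbour order in D8 and patch labelling; boundary-inclusive thresholding
(≥); closed exclusion ball (≤); accuracy cutoff inclusive (≤ 100 m); summer
window inclusive (June 1 – October 31); half-open raster cells (a point on
a cell edge belongs to the north-east cell). Degenerate inputs error early
with informative messages: all-nodata DEMs, single-class training labels,
empty backgrounds, incomplete scenario factorials, empty baseline ranges in
RC. Zero-patch reports return `n_patches = 0` with `NA` means rather than
erroring; a single patch reports an elevation SD of 0.

All randomness flows from one master seed through fixed per-stage offsets
(`stage_seed`), so stages can be rerun independently and whole runs are
bit-reproducible.

## Problem sizes

The shipped tests run the full pipeline at 128×128 cells (1500 trees) for
the parameter-recovery and scenario-monotonicity checks, 96×96 (150 trees)
for pipeline reproducibility, and small closed-form fixtures everywhere
else; oracle-equivalence checks use ≤ 15×15 DEMs and 50×50 patch maps.
At these sizes the landscape comfortably supports the default sampling
design (~950 eligible background cells per 300 presences after
exclusions). Larger landscapes scale linearly in cells for terrain and
projection and n log n for pit filling.

## Known limitations

* The classifier extrapolates poorly outside the training climate range —
  an intrinsic property of tree ensembles, visible under the most extreme
  scenarios once most of the landscape is warmer than any training cell.
* Pseudo-absences may overlap undetected presences; metrics inherit that
  optimism, which the omission-averse threshold partly offsets.
* No dispersal, demography, biotic interactions or microrefugia: a cell is
  "habitat" if its climate envelope matches, nothing more.
* Patch metrics treat the raster grid as truth; patch delineation at 100 m
  cannot resolve corridors narrower than one cell.
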