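---
title: "Methods: ensemble SDMs and range-shift indices on synthetic landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SDMs and range-shift indices on synthetic landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rangedyn implements a complete invasion-ecology range-dynamics study design
— occurrence cleaning, bioclim predictor construction, predictor selection,
gated ensemble species distribution models (SDMs), threshold-based range
maps, and multi-species overlap indices — together with a virtual study
system in which the true niche is known, so that every stage can be
verified quantitatively rather than by eye. This vignette explains the
models and conventions, the tunable parameters, and the design choices made
where the methodology leaves room.

## The virtual study system

`generate_world()` builds, on one lon/lat grid, the inputs the analysis
expects from climate, land-use and topography archives: twelve months of
average/minimum/maximum temperature and precipitation, eight land-use
fraction layers, and a DEM. Spatial structure comes from Gaussian-filtered
white-noise random fields; `corr_length` (cells) is the distance at which
spatial correlation falls to 1/e, and the tests verify it against a
brute-force semivariogram.

Monthly mean temperature at a cell is

    t = t_mean - G(lat) - lapse_rate * elev/1000 + A(lat, x) * cos(2*pi*(m - warm_month)/12) + noise

with three deliberate design features:

* **Concave meridional gradient.** `G` falls as `lat_frac^0.5` (configurable
  via `lat_gradient_shape`): the gradient is steep near the warm edge and
  flattens poleward, so isotherms spread out at the cool edge. A warming
  shift therefore opens disproportionately more newly suitable area than it
  closes — the geometry that produces net range expansion for warm-adapted
  invaders, which is the qualitative regime this analysis targets. A linear
  gradient (`lat_gradient_shape = 1`) makes a shifted thermal band conserve
  its area almost exactly, which is a degenerate test bed for expansion
  indices.
* **Seasonality with structure of its own.** The seasonal amplitude `A`
  increases poleward (`seasonal_lat_gain`) but is also modulated by a
  correlated anomaly field. Without that anomaly, temperature seasonality
  (BIO4) is a deterministic function of latitude — a perfect geographic
  proxy that no real climatology exhibits, and one that short-circuits any
  predictor-importance analysis.
* **Non-degenerate diurnal structure.** The tmax − tmin spread varies
  seasonally and spatially, so BIO2, BIO3 and BIO7 carry information instead
  of collapsing to constants.

Precipitation is a seasonal cycle times a log-normal anomaly field;
land-use fractions are a softmax over eight correlated fields plus a
bare-ground slot, so per-cell sums stay below 1. All randomness is a pure
function of the configuration seed; two calls with the same `world_config`
are bit-identical.

Virtual species are logistic niches over named predictors
(`niche_spec()`): suitability is `plogis(intercept + sum(coef*x) +
sum(quad*x^2))`. The shipped defaults are three-predictor niches — a
quadratic band in annual mean temperature (BIO1) with linear responses to
annual precipitation (BIO12) and urban fraction — with thermal optima in
the middle of the landscape's span and a tolerance of roughly ±1.6 °C at
half-saturation. That width emulates a specialist invader: narrow enough
that presences contrast clearly with background (the recovery experiments
have usable signal), wide enough that suitability grades smoothly over the
map rather than collapsing to a binary ribbon. Occurrences are drawn with
probability proportional to suitability, jittered within cells, and tagged
with a uniform coordinate uncertainty.

What the generator does *not* emulate: coastlines and oceans (every cell is
land), observation bias (an effort layer is deliberately out of the default
design), dispersal limitation, interannual variability, and any internal
structure of climate models — future scenarios are additive temperature
shifts and multiplicative precipitation factors (`scenario_delta()`), which
is exactly the information the analysis consumes. Passing tests on this
system demonstrate that the machinery is correct and directionally
sensitive; they do not certify performance on real, biased, fragmented
occurrence data.

## Occurrence preparation

Records with stated coordinate uncertainty above 5 km are removed
(`filter_uncertainty()`); records with *missing* uncertainty are retained,
because absent metadata is not evidence of error (set `keep_missing =
FALSE` to be stricter). Spatial thinning (`thin_spatial()`) is a randomised
greedy pass: records are visited in a seed-shuffled order and accepted iff
they lie at least 5 km (great-circle, sphere radius 6371 km) from every
accepted record. The output has minimum pairwise distance ≥ 5 km, is
maximal, and is idempotent. The "5 km diameter" is interpreted as a minimum
pairwise distance of 5 km (not a 2.5 km radius); both the distance and the
interpretation are configurable through `thin_km`.

## Predictors

`compute_bioclim()` implements the standard 19 bioclimatic variables with
these conventions, each pinned by a test: seasonality (BIO4, BIO15) uses
the population SD (divisor n) scaled by 100; quarters are the twelve
3-consecutive-month windows with December–January wraparound; temperature
quarters (BIO8–BIO11) are ranked by mean temperature, precipitation
quarters (BIO16–BIO19) by total precipitation, with ties broken toward the
earliest window. `compute_terrain()` uses Horn's 8-neighbour method; aspect
is degrees clockwise from north pointing *downslope*, flat cells carry the
sentinel −1, and east–west spacing is corrected by cos(latitude).
`resample_to()` offers bilinear, nearest and block-mean resampling between
grids. Rasters travel as a light `raster_grid` container (matrix +
geotransform, NA = nodata) and serialize to ESRI ASCII grids — a plain-text
raster exchange format that standard GIS tools read.

## Predictor selection

Collinearity is screened with Pearson correlations at the |r| > 0.7
threshold. By default correlations are computed over all valid land cells
(capped at a deterministic regular subsample); restricting to
presence/background cells is possible by passing `cells`. Zero-variance
predictors have undefined correlations; they are set to 0 with a warning so
that a constant layer can never evict an informative partner.

Importance (`jackknife_importance()`) is the drop in cross-validated AUC
when one predictor is left out of a preliminary model, floored at zero,
with the fold partition held fixed across all leave-one-out runs. The
preliminary model is a single ridge-penalised logistic regression with
linear *and quadratic* terms per predictor. The quadratic terms matter: a
purely linear score cannot represent a band-shaped (unimodal) niche at all,
which drives every importance toward zero and makes the subsequent
collinearity resolution arbitrary. A known consequence of leave-one-out
importance is that members of a redundant cluster shade each other: a
duplicated predictor has importance ≈ 0 (there is a test asserting exactly
this), so importances are comparative evidence within a candidate set, not
absolute effect sizes.

`select_predictors()` resolves conflicts by keeping, within each connected
component of the conflict graph (edges where |r| > 0.7), the subset with
maximum total importance subject to no retained pair conflicting — found
exactly by branch-and-bound for components up to `exact_limit` predictors,
with a deterministic tie-break (larger subset, then lexicographic) and a
greedy fallback above the limit. The naive pairwise rule ("drop the
lower-importance member of each offending pair, strongest pair first") is
*not* equivalent: in a star of conflicts a–b, a–c where importance(a)
exceeds b and c individually but not jointly, the pairwise rule keeps {a}
while {b, c} carries more total importance. The exact subset is what the
pairwise rule is trying to approximate, so it is what the package computes;
the result is invariant to predictor ordering.

## The gated ensemble

For each species the study design is: five pseudo-absence (PA) repetitions
× five 70/30 stratified splits × the algorithm roster, every fit a
candidate ensemble member. PAs are drawn uniformly, without replacement,
from valid non-presence cells; the count is `max(1000, n_presences)` —
1000 background points for species with fewer than 1000 records, otherwise
as many as there are records. (The prose this rule derives from is
grammatically ambiguous; `n_pa_min` makes the floor explicit and
configurable.)

The native roster is four algorithms spanning the main model families:

* `sre` — surface range envelope, the strict BIOCLIM box spanned by the
  training presences (binary scores);
* `glm` — ridge-penalised logistic regression with linear + quadratic
  terms, the conventional parametric member;
* `rf` — random forest (probability votes);
* `xgb` — gradient-boosted trees (logistic objective, single thread for
  determinism).

Each candidate is evaluated on its held-out 30%: rank (Mann–Whitney) AUC
with ties at 0.5, and TSS = sensitivity + specificity − 1 at the held-out
maximum sensitivity–specificity (MSS) threshold — the same thresholding
rule later used for range maps, so gating and binarization are coherent. A
candidate enters the ensemble iff TSS > 0.6 **or** AUC > 0.8. Included
members are combined by a TSS-weighted mean (weights normalised to 1;
equal weighting is available), so the ensemble map is a convex combination
of member maps and inherits their [0, 1] range. A species whose candidates
all fail the gate is recorded as failed and the run continues.

## Ranges and range-shift indices

`mss_threshold()` maximises sensitivity + specificity over the finite
candidate set of midpoints between consecutive sorted unique scores, ties
toward the lower threshold (favouring sensitivity); `binarize()` uses
`score >= threshold`, so the chosen threshold reproduces exactly the
sensitivity/specificity pair that selected it. Identical scores everywhere
is an error ("degenerate scores"), not a silent default. The MSS threshold
is recomputed per species × scenario from that scenario's suitability at
the training presence and PA sites, so thresholds vary across scenarios as
well as species.

Areas are spherical: a cell spanning Δλ with edges φ_b, φ_t has area
R²·Δλ·(sin φ_t − sin φ_b), R = 6371 km. For a current range C and future
range F with shared area S:

* **RER** (range expansion ratio) = F / C — above 1 the potential range
  grows;
* **RSI** (range similarity index) = 2S / (C + F) — a Sørensen overlap, 1
  for identical ranges, 0 for disjoint ones. By this formula *high* RSI
  means similar range positions; prose sources describing the index
  sometimes invert that reading, and the package follows the formula.
* **Expanding range** = cells in F but not C; by construction
  F = S + expanding, an identity asserted in the tests.
* **Centroid shift**: each range's area-weighted centroid is the mean of
  cell-centre unit vectors projected back to the sphere; the shift is the
  great-circle distance and initial bearing between the two centroids.

A paired two-sided t-test across species compares current vs future range
areas when at least two species are configured.

## Multi-species overlaps and hotspots

OIHS is the cell-wise sum of the species' continuous suitability maps; OIPR
is the count of species whose binary range covers the cell; the same
counting operator applied to expanding ranges maps potential co-invasion.
Change maps are `future − current` — the sign convention is chosen so that
positive values mean an increase, matching how "percent of land area with
increasing overlap" is reported (`fraction_area_increasing()`,
area-weighted). Hotspots are cells above the area-weighted 0.9 quantile of
the overlap index (configurable); the quantile mask is reported alongside
the continuous map so no information is lost to the cut-off.

## Determinism and degenerate inputs

Every stochastic step draws from a seed derived deterministically from the
run seed and a purpose tag (species, repetition, stage), so a rerun with an
identical configuration is byte-identical down to the CSV artifacts —
asserted by a test that diffs the files. RNG state of the calling session
is always restored. Degenerate inputs fail loudly and early: degenerate
grid extents, all-zero suitability, all-identical scores, empty ranges,
zero paired variance and empty ensembles each raise a named error rather
than propagating NaN.

## Problem sizes

The recovery experiments run on a 200 × 100-cell landscape (6 arc-minute
cells over 20° × 10°) with 600 sampled occurrences, five PA repetitions ×
five splits, and five seeds — sizes chosen so a full recovery suite
completes in a few minutes on one core while leaving the ensemble ~25
candidate fits per algorithm. Orchestration and determinism tests use a
40 × 35-cell landscape with two repetitions, which exercises identical code
paths at a fraction of the cost. `run_config()` holds every threshold of
the design (5 km cleaning and thinning, |r| > 0.7, TSS > 0.6 / AUC > 0.8,
70/30 × 5 × 5, ≥1000 PAs) with those values as defaults.

## Known limitations

Dispersal is unbounded: a cell is "expanding range" if it becomes
climatically suitable, reachable or not. The envelope member is strict
(no quantile trimming), which makes it conservative near the presence
hull. Jackknife importances shrink under redundancy, as discussed above.
The ASCII-grid interchange format stores no CRS; all grids are assumed
WGS84 lon/lat. And all synthetic-data caveats from the first section
apply: results on this system validate the machinery, not field
performance.
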