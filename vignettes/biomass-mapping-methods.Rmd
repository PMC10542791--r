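---
title: "From airborne LiDAR transects to a wall-to-wall biomass map: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From airborne LiDAR transects to a wall-to-wall biomass map: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amazonagb)
```

## The estimation problem

Airborne laser scanning (ALS) measures forest structure along narrow
transects — here the design is a 12.5 km x 300 m strip sampled at about
4 returns per m² — while a biomass map must cover an entire biome at a
coarse grid (250 m). `amazonagb` implements the chain that bridges the two:

1. **Point-cloud cleaning.** Isolated returns (birds, water vapour, sensor
   noise) are removed with a voxel neighbourhood filter.
2. **Ground classification and terrain.** Ground returns are found by
   progressive TIN densification, a 1-m digital terrain model (DTM) is
   interpolated from them, and the cloud is normalized to height above
   ground.
3. **Canopy metrics.** A 1-m canopy height model (CHM, per-cell maximum
   height) is averaged into 50-m top-of-canopy height (TCH).
4. **Biomass model.** Aboveground biomass density follows the calibrated
   power law `AGB (kg m^-2) = 2 * (0.025 * TCH^1.99)`, converted to
   Mg ha⁻¹ (x 10) and regridded to 250 m.
5. **Extrapolation.** A random forest links the LiDAR-derived 250-m AGB
   cells to twelve satellite covariates (NDVI and EVI q1/mean/q3, L-band
   HH and HV backscatter, mean precipitation, elevation, and the cell
   coordinates X and Y) and predicts a wall-to-wall map. Variable
   importance is the total squared-error reduction per predictor, scaled
   by its maximum and as a percentage of the total.
6. **Uncertainty.** Three calibration uncertainty levels (plot allometry,
   plot sampling, model residual) are propagated by Monte Carlo into a
   50-m SD surface, aggregated to 250 m, and pushed through the
   extrapolation by retraining the forest on resampled responses.
7. **Reporting.** Carbon conversion (x 0.47), reference-map comparison by
   nearest-neighbour resampling under a non-anthropized mask, and
   cell-weighted map summaries (population SD).

Because the real transect archive is hundreds of gigabytes, every stage is
developed and tested against a synthetic-scene generator with complete
ground truth; the generator is first-class, tested code.

## The synthetic scene: what it emulates

`scene_config()` fixes the study conditions. The defaults emulate the
acquisition design at a reduced extent (500 m x 300 m instead of the full
12.5 km, so an end-to-end run takes about a minute):

* **Terrain** — a seeded Gaussian random field low-pass filtered at a 50-m
  correlation length and rescaled to 20 m peak-to-trough relief; 1-m cells.
* **Stand** — homogeneous Poisson stems at 500 ha⁻¹; heights 22 ± 8 m
  (truncated at 2 and 60 m) with 80% of the height variance carried by a
  smooth ~50-m spatial field. The autocorrelation is essential, not
  cosmetic: closed-canopy forests show strongly autocorrelated canopy
  height (site quality, gap-phase dynamics), and a canopy built from
  *independent* heights produces single-column height discontinuities
  whose returns no neighbourhood filter can distinguish from noise.
* **Crowns** — cone-capped cylinders; crown radius `0.5 + 0.12 h`; the
  crown surface falls 15% of tree height from apex to edge. Returns are
  intercepted with probability 0.55 per crown layer; crown echoes are
  top-weighted (25% within an exponential 0.5 m of the surface, the rest
  uniform through the live-crown band, the top 20% of the local surface
  height), matching the occlusion-dominated vertical profile of
  discrete-return sensors. Ground echoes carry 0.15 m Gaussian ranging
  noise, well inside the 0.5 m vertical-accuracy class of the emulated
  surveys.
* **Stem allometry** — DBH couples to height as `3.77 * h^0.52` with
  lognormal scatter, so individual biomass under the default tree equation
  (`0.0673 (rho D² H)^0.976`) scales as `h^1.99`. This makes the synthetic
  world obey the same AGB–TCH power law that the field calibration
  observed; the scale constant was set once against the canopy model and
  frozen. Plot validation therefore closes by construction, as it should
  for an emulator of a *calibrated* system.
* **Covariates** — optical indices are saturating functions of biomass
  plus per-composite noise across 23 pseudo-composites (one year of 16-day
  compositing, so q1/q3 are non-degenerate); HV saturates faster than HH;
  precipitation is a smooth gradient; elevation aggregates the terrain.
* **Outliers** — isolated points injected 10–100 m above the local 4-m
  window maximum of terrain + canopy, pairwise 8 m apart, so each has an
  empty 4-m neighbourhood by construction.

What the generator does **not** emulate: multi-return pulse physics, scan
geometry and swath-edge density variation, radiometry, GNSS error,
understory vegetation layers, and spatially clustered stem placement.
Passing tests therefore demonstrate algorithmic correctness and
recoverability under controlled conditions, not performance on real
archives.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `point_density` | 4 | returns m⁻² | survey design value |
| `voxel_size`, `block_extent` | 1, 4 | m, voxels | 4-m cube neighbourhood of the outlier filter |
| `min_neighbors` | 5 | count | isolation threshold; a return with exactly 5 neighbours survives |
| `seed_cell_size` | 10 | m | neighbourhood-minima seeding of the ground TIN |
| `max_distance` | 1.0 | m | TIN densification distance criterion |
| `max_angle` | 6 | degrees | angle subtended at the nearest facet vertex |
| `noise_floor` | 0.45 | m | angle criterion waived below 3x ground-noise SD |
| `seed_spike_tolerance` | 5 | m | rejects canopy seeds from fully occluded cells |
| CHM / TCH / map cells | 1 / 50 / 250 | m | product resolutions |
| `min_valid_fraction` | 0.9 (50 m), 0.5 (250 m) | fraction | coverage rules; looser at 250 m because transects only partly cover edge cells |
| `a`, `b`, `scale` | 0.025, 1.99, 2 | — | TCH power law |
| `n_trees`, `mtry`, `min_leaf` | 500, ⌈p/3⌉, 5 | — | forest defaults, seeded |
| carbon fraction | 0.47 | — | biomass-to-carbon conversion |
| `n_maps` | 1000 | count | operational Monte Carlo size; convergence studies use 25 vs 100 |

## Design decisions worth knowing about

**Outlier neighbourhood.** The isolation test counts the other returns in
each return's 4 m x 4 m x 4 m voxel cube. Two anchorings are provided.
The default, `"centered"`, centres the cube on the return (exact Chebyshev
query, O(n) via voxel hashing): every return sees its full physical
neighbourhood. The `"lattice"` alternative partitions space into fixed
aligned cubes; it is a single counting pass, but a return near a cube
corner is cut off from most of its physical neighbours, and on synthetic
transects this removes several percent of genuine canopy and ground
returns in thin strata (we measured returns with >30 neighbours within
4 m but <5 in their anchored cube). The centred form is the one under
which the filter's published intent — remove *isolated* points — holds
with <1% collateral loss at 4 returns m⁻².

**Ground filter.** Seeds are the lowest return per 10-m cell; a seed more
than 5 m above the median of its neighbouring seeds is rejected, because a
fully occluded cell has no ground echo and its minimum is a crown return
that would otherwise spike the DTM by tens of metres. Densification
accepts a candidate when its vertical distance to the TIN facet is at most
1 m and either that distance is below the 0.45-m noise floor or the angle
subtended at the nearest facet vertex is at most 6°; the noise-floor
waiver exists because at sub-noise offsets the subtended angle measures
ranging error, not terrain shape. Candidates outside the current hull are
tested against the nearest hull vertex so the TIN can grow into the
transect edge. The TIN itself is an incremental Bowyer–Watson Delaunay
triangulation with walk-based point location (compiled code), which is
what makes progressive densification O(n log n)-ish rather than a full
retriangulation per iteration.

**DTM and normalization.** The DTM is linear interpolation on the
ground-return TIN at cell centres; the thin strip outside the convex hull
is filled by nearest-ground-return elevation so normalization never hits
nodata. Normalization subtracts the *containing* DTM pixel (not bilinear),
so slightly negative normalized heights are expected and the CHM floors
them at zero.

**Order of operations.** TCH is averaged at 50 m first and converted to
biomass second. Because the power law is convex (exponent 1.99), the
alternative order is systematically higher (Jensen); a property test
documents the direction.

**Uncertainty semantics.** Replicate seeds derive from the master seed by
a counter (`seed + replicate`). The extrapolation forest keeps a *fixed*
seed across replicates: the Monte Carlo measures uncertainty propagated
through the response draws, not the forest's own bootstrap noise, and with
zero input SD the output SD is exactly zero. Normal draws are truncated at
zero (biomass cannot be negative) and the truncated fraction is reported.
The 50-to-250-m SD aggregation uses the block mean (full within-block
correlation), the conservative choice given the strong spatial correlation
of canopy structure at 250 m; `method = "independent"` gives
`sqrt(mean(sd²)/n)` instead.

**Statistics conventions.** The rank-sum test reports both the
Mann–Whitney U and the classical rank-sum W (`W = U + n_x(n_x+1)/2`);
exact enumeration is used for tie-free designs up to `n_x n_y = 400`,
otherwise the tie-corrected normal approximation with continuity
correction. Quartiles of covariate time series interpolate order
statistics (type 7). Map summaries are cell-weighted and use the
population SD; both choices are documented because neither is derivable
from the products themselves.

**Serialization.** Point clouds round-trip through LAS 1.2 (point format
0; coordinates quantized at 0.01 m; ground = class 2, outliers = class 7,
with 18 also read as outlier). LAZ is not supported. Gridded products
serialize to ESRI ASCII grid with a CRS sidecar; intermediates stay in the
projected working CRS and final map products are conventionally tagged
EPSG:4326.

## Numerical choices

* Incremental Delaunay uses double-precision orientation/in-circle
  predicates with walk location and an exhaustive-scan fallback;
  duplicate XY vertices (possible after LAS quantization) are skipped on
  insertion.
* Monte Carlo SDs accumulate deviations from a baseline replicate; the
  naive sum-of-squares form loses all significant digits exactly in the
  zero-noise regime the collapse tests probe.
* Power-law refits (`minpack.lm::nlsLM`) are bounded
  (`a` in [1e-6, 10], `b` in [0.1, 5]); a failed refit discards the
  replicate, and more than 20% failures aborts with an error.
* Negative map predictions are clamped to zero; empty aggregation blocks
  and blocks under the coverage threshold become nodata rather than biased
  means.

## Problem sizes used by the test-suite and acceptance runs

Unit tests run on 200 m x 100 m scenes (~80k returns); the full-scale
checks use the default 500 m x 300 m transect at 4 returns m⁻² (~600k
returns), a 10 km x 10 km regional biomass field at 250 m for model
recovery, and 25-vs-100-map convergence for the satellite Monte Carlo —
sizes chosen so a complete run finishes in a few minutes while keeping
every estimate's sampling error far from its acceptance margin. The
operational `n_maps = 1000` remains the default for real use.

## Known limitations

* The three stem allometries shipped in `allometry_registry()` are
  documented stand-ins from the pantropical literature; site-calibrated
  equations should be supplied for real analyses.
* CHM apex heights underestimate true tree heights by ~0.5–1 m at
  4 returns m⁻² because the top metre of a crown is often unsampled; this
  is sensor physics, and the relevant tests score the median deficit and a
  2-m band rather than pretending the gap away.
* The ground filter's defaults are tuned for undulating terrain under
  tall closed-canopy forest; very steep terrain (slopes approaching the
  6° angle criterion over 10-m seed spacing) would need a larger
  `max_angle` and a smaller `seed_cell_size`.
* `validate_against_field()` assumes plots and clouds are co-registered
  (DGPS-grade positioning); no co-registration search is attempted.
* Real-data performance claims (map statistics, fit quality of the
  published map) are out of scope: they require the full transect archive.
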