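---
title: "Methods: height-dependent drought mortality from synthetic forest landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: height-dependent drought mortality from synthetic forest landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treemort)
```

# The problem and the model

Individual-tree mortality during extreme drought can be measured at
landscape scale by combining a LiDAR canopy height model (CHM) — which
locates each tree and gives its height `Z_TREE` — with repeated multiband
aerial imagery that reveals whether each crown is alive or dead. Two
statistical summaries matter:

1. **Mortality risk**: a binary dead/live outcome per tree, modelled by
   multivariable logistic regression on standardized covariates (height,
   maximum vapor pressure deficit, temperature and precipitation anomalies,
   soil available water storage, stand cover, slope). Standardization makes
   the coefficients comparable; exponentiating them gives odds ratios per
   SD, which the pipeline also rescales to physical increments (per 10 m of
   height, per 0.4 kPa of VPD, …). With low baseline mortality (< 3 %) the
   odds ratio approximates relative risk; the report flags whether that
   condition holds.
2. **Mortality rate**: the percent of susceptible trees dying per year. Its
   dependence on height within bins of an environmental gradient gives the
   height-mortality slope β_MORTALITY-HEIGHT, and regressing those slopes
   on the gradient estimates the interaction model on the rate scale,

   `M = β0 + β1 · Z_TREE · Δ_ENV`.

   β1 > 0 means the environment preferentially kills tall trees.

The package implements the full chain and, because real imagery cannot ship
with it, a seeded synthetic-forest generator whose ground truth every stage
is tested against.

# The synthetic world

The generator's defaults are fixed once and are not tuned to test outcomes.

* **Stand structure.** Trees are placed by sequential random inhibition
  (candidates closer than `min_spacing_m`, default 4 m, are rejected);
  simple inhibition is the minimal point process with a realistic minimum
  stem spacing. Requested densities beyond the random-sequential-adsorption
  packing bound are refused up front with the achievable count. Heights are
  truncated log-normal (log-mean `log(18)`, log-sd 0.55, truncated to
  5–60 m) — a right-skewed stand spanning all three height classes, drawn
  by inverse CDF so the random-number stream length does not depend on the
  truncation. Crowns are cones with radius 0.10 m per metre of height,
  matching the conical, little-overlapping crowns of the conifer forests
  this analysis suits; the CHM is the pixel-wise maximum of the cone
  surfaces at 0.6 m resolution.
* **Environment.** Maximum VPD is a planar ramp (1.2 → 2.4 kPa) plus smooth
  Gaussian noise. The temperature and precipitation anomaly fields are
  affine functions of the realized VPD field plus smooth residual noise
  that is explicitly orthogonalized against it, so the realized
  correlations equal the targets (0.98 and 0.96, the values this kind of
  drought gradient exhibits) exactly rather than in expectation. Soil water
  storage and slope are independent ramp-plus-noise fields; percent cover
  is derived from the rendered CHM (pixels above 5 m, aggregated cells).
* **Mortality process.** An annual per-tree hazard in one of two forms:
  logistic in height and environment (`logistic-status`), or a linear
  mortality rate in % yr⁻¹ (`linear-rate`) housing the `β1·Z·Δ_ENV`
  interaction directly. Probabilities are clamped to `[ε, 1−ε]` (a clamp of
  0 is allowed, so a degenerate hazard can kill nobody); out-of-range raw
  values are tallied in a warning, never fatal. Death is absorbing. All
  trees are alive at the first acquisition; acquisition years default to
  2009, 2010, 2012, 2014, 2016 — five analysis dates with the 2-year late
  period spacing that motivates dividing late-interval mortality by two.
* **Imagery.** Each crown pixel is labelled by its owner's status crossed
  with illumination: the half-crown toward the sun azimuth (default 180°)
  is sunlit. Pixels exactly on the divide are split by the perpendicular
  coordinate so the halves differ by at most one pixel; near-zero dot
  products (floating-point jitter at the divide and at the crown-radius
  boundary) are snapped to zero to keep the geometry symmetric. Band values
  are drawn from 4-band Gaussians per class; the default means emulate
  red/green/blue/NIR digital numbers (live = NIR-bright, dead = red-grey,
  shading halves brightness) with sd 5 — separable but not trivially so.

What the generator does **not** emulate: radiative-transfer reflectance,
atmospheric or radiometric variation between years, species mixtures,
irregular or overlapping deciduous crowns, spatially autocorrelated death
(beetle patches), and recruitment. A green end-to-end test therefore
establishes that the pipeline's inference is correct when its geometric and
spectral assumptions hold, not that those assumptions hold for any
particular sensor.

# Crown detection and segmentation

Treetops are local maxima of the CHM within a circular window whose radius
scales with candidate height, `max(1.5 m, 0.05·h)` — the CHM tree-detection
literature uses height-scaled windows but no universal constant, so the
coefficients are configurable defaults. Ties on plateaus go to the smallest
`(row, col)`, making output deterministic and row-major ordered.

Crowns are the watershed catchments of the inverted CHM seeded at the
treetops, restricted to the mask `CHM ≥ 5 m` (the analysis floor; the small
height class starts at 5 m). The implementation is a priority flood in
C++: pixels are claimed in order of decreasing height, ties going to the
lower label, 4-connected — equivalent to marker-based watershed and fully
deterministic. Two repairs keep the crown map a partition of the mask:
above-threshold components that contain no marker get their highest pixel
promoted to an apex (counted in a warning), and catchments smaller than 3
pixels are merged into the neighbouring crown with the highest shared-border
CHM (noise-maximum suppression). `validate_crown_map()` asserts the
partition, one-apex-per-crown, apex-equals-maximum and 4-connectivity
invariants and is run inside the tests.

One segmentation (the single-date CHM) is reused for every acquisition
year; only crown *status* changes through time. Re-segmenting each year
would break crown identity across years.

# Classification and the dieback threshold

Pixel classification is Gaussian maximum likelihood: per-class sample means
and covariances (ridge-regularized by `1e-6·trace/4` on the diagonal when
near-singular), equal priors by default since training-set class
proportions are an artefact of sampling, and argmax of log-density plus
log-prior with ties to the lowest class index. Pixels with non-finite bands
fall back to the background class and are tallied. The tests check the
classifier against a direct per-class density evaluation, not another
library.

Crown dieback is the mean of the binary dead raster over the crown's
pixels; a crown is dead when dieback strictly exceeds 0.375. The threshold
calibration sweeps a grid (step 0.025) over [0, 1] and picks the
accuracy-maximizing threshold, breaking near-ties (within 0.005) by the
smallest `|FPR − FNR|`, then by the smaller threshold. "Unbiased" is not a
standard term for a classification threshold; balancing false-positive
against false-negative rates at near-tied accuracy is this package's
interpretation, and the overall-accuracy metric is likewise a
decision — the calibration literature this emulates does not state whether
its validation set was balanced.

# Temporal tracking

Records join the fixed segmentation with per-year statuses, sample every
environmental raster at the crown centroid (nearest pixel), and enforce the
absorbing state: classifier flicker (dead → live) is coerced back to dead
with a warning count. Height classes are half-open — small [5, 15), medium
[15, 30), large [30, ∞) — because the natural-language bounds ("15–30 m")
overlap at the boundaries and a partition is required; 15 m is medium,
30 m is large.

Mortality per interval is newly-dead over susceptible-at-start × 100, the
rate divides by the interval length, and dead trees leave the pool so rates
are never inflated by re-counting. Groups with an empty pool get `NA`
(flagged), not 0 — a 0 would be a claim, `NA` is an absence. Rate CIs use
the normal approximation to the binomial, the standard choice when the
underlying error-bar method is unstated. Conservation (initial n =
susceptible + cumulative dead) is asserted as a property test at every
acquisition.

# Driver models

Covariates standardize to mean 0, SD 1 after transforms: log for height,
log1p for slope (slope can be 0), identity otherwise; temperature and
precipitation enter as percent anomalies against configured historical
normals (the generator already produces anomalies, so conversion is only
applied when normals are supplied). Transform metadata is retained for
exact round-trips and unit back-conversion. Collinearity is screened with
VIFs (flag at 2); the VPD–temperature–precipitation trio fails by
construction, which motivates the reduced model that drops the anomaly pair
and lets VPD carry the climate signal.

The logistic fit is IRLS written in the package (tolerance 1e-8 on the
largest coefficient change, 50 iterations maximum, SEs from the observed
information); `stats::glm` is used in the tests as an independent
cross-check, never as the implementation. Complete separation surfaces as a
non-convergence error naming the diverging variable. Effects per physical
increment are computed by rescaling the standardized coefficient to the
covariate's natural scale; for log-transformed covariates this is a local
linearization at the covariate mean, flagged `linearized` in the output,
because a constant per-10 m odds ratio is not strictly compatible with a
log-height model — the report makes the approximation explicit rather than
hiding it. The default increments (10 m, 0.4 kPa, 2.9 % ≈ 0.4 °C, −4 % ≈
35 mm, 6.2 mm, 17 %) are treated as roughly 1 SD of each covariate in a
real stand and are configurable.

Binned mortality rates divide by 2 for the 2-year acquisition lag, capping
rates at 50 % yr⁻¹ by construction; bins under 25 trees are excluded and
counted. The rate model is weighted least squares with bin tree counts as
weights — whether the original analysis weighted its bins is not stated, so
weighting by sample size is this package's choice (and a zero-weight row
provably changes nothing). "Bivariate logistic regression" alongside
"multiple … model" phrasing is ambiguous; it is implemented here as one
multivariable binary-outcome logistic model.

# Height-slope meta-regression

Within each environmental bin (default: 15 equal-width bins spanning the
1st–99th percentile, since the original bin widths are not printed),
mortality rate per 5 m height bin is regressed on the height-bin centre,
weighted by trees per bin; bin centres rather than tree-level heights match
the sample-size-weighted formulation. Bins with fewer than 3 occupied
height bins are skipped and logged. An exact fit reports σ = 0 with p = 0
for a non-zero slope and p = 1 for a zero slope, so noiseless constructions
behave sensibly.

The slopes, filtered to p < 0.05 ("significant" is unqualified in the
source analysis, so α = 0.05), are regressed on the bin centre with
inverse-variance weights. The source conflicts with itself on the scheme —
σ⁻¹ in the text, 1/σ² in the figure caption — so both are implemented;
1/σ² is the default and the analysis scripts log the delta between them.
Zero σ becomes a large finite weight (1e12 × the largest finite weight) so
exact slopes remain usable; infinite σ becomes weight 0, and removing such
a point provably changes nothing. Weighted R² is `1 − SSE_w/SST_w` with the
weighted mean in SST. The cover analysis fits the two sides of a 50 %
breakpoint independently; a side with fewer than 3 significant slopes is
reported unfittable rather than erroring, and bins exactly at the
breakpoint go below, so a breakpoint at the data maximum degenerates to the
single-segment fit.

# Numerical and testing notes

* Rasters are plain matrices with a `res` attribute (no geospatial raster
  package is assumed); row/col follow the top-left origin with pixel-centre
  sampling.
* All randomness is seeded; identical seeds give bit-identical landscapes,
  CHMs, imagery and fits.
* Simulation-scale property tests are run at reduced size to keep the suite
  fast: CI-coverage of generator coefficients at 20 replicates × 30,000
  trees (coverage is sample-size invariant), the interaction-recovery check
  at 3 seeds × 150,000 trees, null-hazard replicate suites at 20 draws. The
  headline effect-size recoveries in the acceptance tests run at the full
  200,000 trees.
* The joint null-hazard check uses a likelihood-ratio test plus
  Bonferroni-widened per-coefficient intervals; requiring seven separate
  95 % CIs to all cover the null simultaneously would fail by design about
  a third of the time, and more often when the climate trio's VIFs exceed
  30.
* The interaction recovery is attenuated a few percent by binning (within a
  5 m height bin the weighted mean height is not the bin centre for skewed
  height distributions); the tests budget 10 % relative error for it.

# Known limitations

* Watershed boundaries, and hence crown pixel counts, depend on the
  deterministic tie rule; other implementations draw equidistant boundaries
  differently.
* The per-increment odds ratio for log-transformed covariates is a local
  approximation at the covariate mean (flagged in output).
* No spatial autocorrelation correction in the driver models, no
  survival-time modelling, no multiple-testing adjustment across drivers,
  and no formal breakpoint estimation for the cover analysis — all outside
  the analysis this package reproduces.
* The unequal-interval cadence (a 4-year gap in the middle of the series)
  is handled by dividing by the actual interval length; the acquisition
  list is configurable where a different cadence is wanted.
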