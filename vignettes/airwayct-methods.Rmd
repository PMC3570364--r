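---
title: "Airway wall thickness and emphysema quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airway wall thickness and emphysema quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(airwayct)
```

## The measurement problem

Airway wall thickening and parenchymal destruction (emphysema) both
contribute to airflow limitation in smokers, and both are visible on
chest CT. Measuring them reliably is hard for two reasons. First, the
airways whose caliber matters most — internal diameters around
3–4 mm — have walls of 0.4–0.9 mm, close to the voxel size of a
screening CT (≈ 0.6 × 0.6 × 0.7 mm) and below the width of the
reconstruction point-spread function. Any edge-to-edge thickness
measure (e.g. full width at half maximum) is then dominated by blur
and systematically overestimates thin walls. Second, single hand-picked
bronchi generalize poorly; a whole-lung summary needs many locations,
an explicit rule for which locations are measurable, and a weighting
that reflects how much perimeter was actually assessed.

`airwayct` addresses both with an integral-based wall measure at a
fixed internal lumen diameter (default 3.5 mm), aggregated over all
detectable locations in all five lobes with assessed-perimeter-fraction
(APF) weighting, alongside trachea-recalibrated densitometry (Perc15,
%LAA−950, lung volume).

## Wall thickness by HU integration

At equally spaced positions (default 1 mm, both centerline endpoints
included) along each airway centerline, the volume is resampled in the
plane perpendicular to the local tangent: `n_rays = 32` radial
profiles, 6 mm long, sampled every 0.1 mm by trilinear interpolation.
Per ray:

1. **Inner border**: the smallest radius where the normalized profile
   `(HU(r) − HU_air) / (HU_peak − HU_air)` crosses 0.5 rising, with
   linear sub-step interpolation. `HU_air` is the median HU at the
   section center; `HU_peak` the section-level median of per-ray
   maxima. For a symmetric blurred edge the half-maximum stays at the
   true border; normalizing by the *blurred* peak guarantees a crossing
   even when a sub-voxel wall never reaches soft-tissue density.
2. **Wall integral**: with the wall peak at `r_peak` (the onset of the
   region within a noise-adaptive tolerance of the profile maximum, so
   plateaus from adjacent tissue anchor at their leading edge), the
   baseline is lumen air before `r_peak` and parenchyma after, and

   `t = h · Σ clip( (HU(r) − b(r)) / (HU_wall − b(r)), −0.25, 1.25 )`

   over `[r_inner − 2 mm, r_peak + 2 mm]`. `HU_wall` is a fixed
   soft-tissue reference (0 HU). Because convolution preserves the
   integral, `t` is insensitive to the PSF width — the package's
   phantom tests show < 0.01 mm shift across FWHM 0.5–1.0 mm. The clip
   bounds are deliberately symmetric around the baselines: a hard
   `[0, 1]` clip would rectify zero-mean image noise into a
   dose-dependent thickness bias of several microns, which is exactly
   the kind of artifact a dose-agreement analysis must not contain.
   A fixed `HU_wall` (rather than the blurred per-section peak) is
   essential for the same reason the integral is used at all: for
   0.4–0.9 mm walls under protocol blur the observed peak is 40–60% of
   the true wall density, and normalizing by it would inflate
   thickness by the same factor.
3. **Outer border / APF**: the outer border counts as detectable when
   the profile falls below
   `HU_par + f_out · (HU_peak − HU_par)` (default `f_out = 0.5`)
   within `d_max = 2 mm` beyond the wall peak. Adjacent tissue of
   wall-like density (vessels) keeps the profile high, so those rays
   are unassessed. `apf_local` is the assessed fraction of rays; the
   per-location AWT averages assessed rays only.
4. **Internal diameter**: twice the mean inner radius over rays with an
   inner border (an elliptical lumen therefore yields the mean-radius
   diameter, not the equal-area one). On assessed rays the inner
   radius is refined as `center − t/2 + σ²/(2R)`: the centroid of the
   wall integrand and the integral thickness are both blur-invariant
   in 1D, and the `σ²/(2R)` term undoes the inward centroid shift an
   isotropic PSF produces on a curved wall (σ is recovered per ray
   from the blurred wall's own peak-amplitude/width relation
   `A = 2Φ(t/2σ) − 1`). Without this refinement the raw half-maximum
   radius is ~0.2 mm low for sub-voxel walls, enough to misclassify a
   true 3.5 mm airway into the 3.0 mm diameter class.

Locations are retained when the internal diameter is within
`3.5 ± 0.25 mm` and `apf_local ≥ 0.25`. Lobar AWT is the APF-weighted
mean over locations, and the whole-lung AWT_3.5 is the APF-weighted
mean over the five lobes (the symmetric five-lobe formula; locations,
not branches, are the unit of analysis). Profiles are smoothed with a
symmetric 3-tap mean before detection — it suppresses noise in the
border and peak decisions without moving edges or changing the
integral. Cross-sections within 2 mm of a bifurcation, plus one local
lumen radius, are skipped: perpendicular planes are ill-defined there
and extracted paths cut the junction corner.

## Centerline extraction

The lumen mask's voxel graph (26-connectivity, Euclidean edge weights)
is decomposed by iterative farthest-point geodesic paths from the
trachea root (most cranial, most central lumen voxel). Paths are routed
on centrality weights — edge length divided by `1 + r²` with `r` the
local radius from a geodesic distance transform — which pulls them onto
the medial axis; Euclidean distances decide who is farthest and whether
a candidate branch is genuine (it must extend beyond
`max(3 mm, 2·r_attach + 1 mm)`, so bulges of wide airways do not spawn
spurious branches). The union of paths is split at junctions into
branches; generation is topological depth, 0 at the trachea (1 at the
root for masks without a trachea label). Each branch is resampled at
0.6 mm and recentred to sub-voxel accuracy by perpendicular-slab
centroids of the lumen (straight-cylinder RMS error < half a voxel in
the tests). Anatomical (Boyden) naming is out of scope; generations
are purely topological.

## Densitometry

All HU are first shifted so mean tracheal air is −1000 HU; the air mask
is eroded by up to two voxels so partial-volume rim voxels do not bias
the reference. Perc15 is the 15th percentile of parenchymal HU under
the interpolated-order-statistic convention (quantile type 7 — the
definition fixes the percentile, not the convention, so the package
states one and tests it against a sort-based oracle). %LAA−950 counts
voxels below −950 HU; values below 0.1% are floored before the natural
log so emphysema-free subjects stay finite. The parenchymal mask is
the lobe labels minus the lumen dilated by one voxel; exclusion happens
before the percentile denominator. Lung volume is voxel count × voxel
volume.

## The digital phantoms

`rasterize_phantom()` draws airway trees (straight branches, known
lumen diameter, wall thickness, lobe, generation) into a textured
parenchyma and images them with the screening-protocol model: in-plane
Gaussian PSF (default FWHM 0.7 mm, the soft-kernel surrogate), boxcar
averaging over the 1 mm slice thickness at 0.7 mm increment, and
additive Gaussian noise (25 HU low dose, 10 HU high dose; only the
ordering matters). Tissue defaults: lumen/trachea air −1000 HU, wall
0 HU, parenchyma −880 ± 20 HU, emphysema −980 ± 10 HU — physiologic
values consistent with the −950 HU threshold; the textures are clamped
clear of −950 so the phantom's low-attenuation set is exactly its
emphysema voxel set. Three rendering choices matter for validity:

* walls and lumens are painted with partial-volume (linear coverage)
  blending — binary voxel painting inflates a 0.6 mm annulus by ~7% at
  protocol spacing, which would corrupt the recovery benchmark;
* emphysema is placed as spherical blobs (radius 2–6 mm) trimmed to the
  requested voxel fraction, giving spatially coherent low-attenuation
  areas whose realized fraction is recorded in the truth;
* simulated HU are not quantized or clipped after noise: clipping air
  at the −1024 storage floor is nonlinear in a calibration drift and
  would break the exact drift-equivariance that trachea recalibration
  is designed to provide.

The phantoms emulate geometry, blur, noise, drift and tissue contrast.
They do **not** emulate scanner physics (beam hardening, spiral
artifacts, dose modulation), respiratory motion, mucus, oblique
non-circular lumens, or real lobe anatomy (lobe labels are generated,
not segmented). Passing recovery tests on phantoms therefore shows the
algorithm is unbiased under the imaging model, not that segmentation
or anatomy-driven errors are absent in clinical data.

The five-lobe template is a rooted bifurcating tree: trachea → main
bronchi → lobar bronchi (with a bronchus intermedius on the right) →
binary subtrees. Per-generation diameters must be strictly decreasing;
the default map places the largest cumulative branch length in the
3.25–3.75 mm class, so the APF sweep's optimum reproduces the
fixed-diameter choice of 3.5 mm. The sweep breaks ties toward the
smaller diameter (closer to the flow-limiting periphery).

## The synthetic cohort

`simulate_cohort()` generates a heavy-smoker screening cohort: age
59.4 ± 5.2 y; log-normal pack-years with median 34.0 and quartiles
28.0–45.6; 59.1% current smokers; log-AWT and Perc15 bivariate normal
with medians 0.57 mm and −920 HU and SDs derived from the published
quartiles via the normal-IQR identity `IQR = 2·z(0.75)·sd`;
FEV1%predicted generated linearly,

`FEV1%pred = β₀ − 31.28·log(AWT) + 0.342·Perc15 + ε`,

with β₀ solved so the mean is 98.2 at the covariate means and the
residual SD solved so the total SD is 19.7. Respiratory symptoms are
Bernoulli draws from per-symptom logistic models on log-AWT (slope
+1.5 per log-mm — the direction "thicker walls in symptomatic
subjects"; published prevalences fix the intercepts, but no odds
ratios are published, so the slope is a free parameter). %LAA−950 is a
fixed monotone decreasing log-linear map of Perc15 calibrated to
median 2.5% and quartiles 1.3–4.3. FEV1 (liters), FEV1/FVC and CT lung
volume are descriptive transforms calibrated to the published means
and are not part of the structural model.

One parameter is a documented assumption: the log-AWT/Perc15
correlation `rho_awt_perc15 = +0.20`. No published value exists; the
sign follows the positive univariate association between log-AWT and
Perc15 (airway-predominant disease with relatively preserved
parenchyma), and the magnitude encodes "significant but weak". Under
these defaults the sequential variance decomposition of FEV1%predicted
attributes ≈ 30% to log-AWT and ≈ 9.5% to Perc15, with total R² ≈ 0.39.

## Statistics

Descriptives are mean ± SD or median (25th–75th percentile, type-7
quantiles); group comparisons use Mann-Whitney U (exact for small
tie-free samples — verified against exhaustive enumeration up to n = 7
per group — otherwise the continuity-corrected normal approximation),
Student's t, chi-square, and the Wilcoxon signed rank for paired lobar
comparisons. OLS is ordinary `lm()` with natural-log transforms where
declared; the multivariate entry rule (univariate p < 0.05) is provided
as a helper. Variance explained is reported under **both**
decompositions — sequential R² increments in entry order (which always
sum to the model R², and are the headline) and squared semipartial
correlations from the full model; the two coincide only for orthogonal
predictors, and semipartials may legitimately sum above R² under
mutual suppression, which the default cohort exhibits. No
multiple-testing correction is applied (two-sided p < 0.05
convention). Bland-Altman agreement reports bias, 1.96·SD limits, the
95% CI of the bias, and a one-sample t p-value. Missing data are
dropped listwise per analysis.

## Problem sizes and determinism

The test-suite and acceptance runs use: single-tube phantoms of
20–30 mm on ~40–46 mm fields at exact protocol spacing
(0.586 × 0.586 × 0.7 mm); 20 tubes for the recovery benchmark; 8 dose
pairs; a 63–77-branch five-lobe tree on a ~180 mm field for the
diameter sweep; cohorts of n = 492 with 40 seeds for parameter
recovery. These sizes make every claim reproducible on a laptop in
minutes while keeping the voxel geometry identical to the full-size
protocol. Every stochastic stage takes an explicit integer seed and
restores the caller's RNG state; identical seeds give bit-identical
phantoms, cohorts and measurement tables.

## Known limitations

* Branches are straight cylinders; curvature- and taper-induced biases
  are not probed by the phantoms.
* The internal-diameter convention (2 × mean ray radius) differs from
  the equal-area diameter for elliptical lumens; phantoms are circular,
  so the tests do not constrain strongly elliptical airways.
* The centerline extractor assumes a single connected lumen rooted at
  the trachea; disconnected segmentations are rejected rather than
  repaired.
* Lobe assignment of extracted branches uses the majority lobe label
  near the distal tip; with the phantom's generated labels this is
  exact, but real lobar boundaries near fissures would be noisier.
* The cohort simulator reproduces marginals and the linear structural
  model, not the full joint distribution of a real screening
  population (no height/sex/selection effects, no longitudinal smoking
  history).
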