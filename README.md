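# airwayct

Quantification of airway wall thickness and emphysema on (low-dose)
chest CT, for pulmonary imaging researchers who want standardized,
whole-lung airway measurements rather than a handful of hand-picked
bronchi.

## What it computes

**Airway wall thickness at a fixed internal lumen diameter (AWT_3.5).**
Airway centerlines are extracted from a lumen segmentation; the volume
is resampled in planes perpendicular to each branch; on every radial
profile the inner border is detected at the half-maximum crossing and
the wall thickness is measured by integrating Hounsfield units across
the wall,

    AWT = h * sum( clip( (HU(r) - b(r)) / (HU_wall - b(r)) ) ),

with `b(r)` the lumen-air baseline before the wall peak and the
parenchymal baseline beyond it. Because a (symmetric) reconstruction
blur preserves this integral, the measure avoids the systematic
overestimation that full-width-at-half-maximum methods suffer for
sub-voxel walls. A cross-section's **assessed perimeter fraction
(APF)** is the fraction of rays on which the outer border is detectable
(no adjacent tissue of wall-like density); locations with APF < 25% are
excluded, measurements are kept where the internal diameter is
3.5 ± 0.25 mm, and lobe and whole-lung values are APF-weighted:

    AWT_lung = sum_lobes( AWT_lobe * APF_lobe ) / sum_lobes( APF_lobe ).

**Emphysema densitometry.** After shifting all HU so mean tracheal air
is −1000 HU (trachea recalibration), the package reports Perc15 (the
HU below which 15% of parenchymal voxels fall), %LAA−950 (the
percentage of voxels below −950 HU, with natural-log transform), and
the CT lung volume, with airway lumina excluded from the parenchymal
distribution.

**Supporting machinery.** Digital CT phantoms (airway trees with known
lumen diameter, wall thickness, lobe and generation, embedded in
textured parenchyma with controllable emphysema, imaged with the
screening-protocol geometry: 512×512 matrix at FOV 300–350 mm, 1 mm
slices at 0.7 mm increment, soft-kernel blur, dose-dependent noise); a
synthetic heavy-smoker cohort generator calibrated to published
population descriptives; an APF-maximizing diameter sweep
(2.5–5.0 mm); and the statistical layer (descriptives, rank tests,
univariate/multivariate OLS with variance partitioning, Bland–Altman
agreement).

## Worked example

Measure a noisy digital phantom — a 3.5 mm lumen, 0.6 mm wall tube at
protocol voxel spacing with 25 HU noise — end to end:

```r
library(airwayct)

acq  <- acquisition_cropped(40, noise_sd_hu = 25, seed = 1)
tree <- single_tube_tree(lumen_diameter_mm = 3.5, wall_thickness_mm = 0.6,
                         length_mm = 20)
ras  <- rasterize_phantom(tree, phantom_truth(seed = 2), acq)

locs <- measure_airways(ras$ct, ras$labels)      # centerlines -> sections
sel  <- select_fixed_diameter_locations(locs)    # 3.5 +/- 0.25 mm, APF >= 25%
agg  <- aggregate_lobes(sel)
#> locations: 16  diameter: 3.48 mm  AWT: 0.608 mm  APF: 16.0
```

The measured wall (0.608 mm) recovers the 0.6 mm truth to ~0.01 mm
despite the blur and noise, and the internal diameter lands in the
3.5 mm class. Densitometry on the same phantom:

```r
quantify_densitometry(ras$ct, ras$labels)
#> Perc15: -896.0 HU  LAA-950: 0.13%  shift: 7.7 HU
```

Perc15 sits where the −880 ± 20 HU parenchyma texture puts its 15th
percentile; the recalibration shift undoes the simulated drift. The
cohort and regression layer:

```r
cohort <- simulate_cohort(default_params(seed = 7))
multivariate_ols(cohort, "fev1_pct_pred", c("log_awt35", "perc15_hu"))
#> OLS: fev1_pct_pred ~ log_awt35 + perc15_hu  (n = 492, R^2 = 0.394)
#>          term coefficient std_error   p_value
#> 1 (Intercept)    405.3424  36.81797 2.463e-25
#> 2   log_awt35    -29.4816   1.72615 1.237e-51
#> 3   perc15_hu      0.3527   0.04026 3.183e-17

variance_explained(cohort, "fev1_pct_pred", c("log_awt35", "perc15_hu"))
#>        term sequential_r2 semipartial_r2
#> 1 log_awt35     0.2987686      0.3615536
#> 2 perc15_hu     0.0951401      0.0951401
```

Thicker airway walls predict lower FEV1%predicted, and log-AWT explains
about three times the outcome variance that Perc15 does — sequential
shares of ~30% and ~10%.

A thin command-line wrapper over the same functions ships in
`inst/cli/airwayct.R`:

```sh
Rscript inst/cli/airwayct.R cohort-sim --n 492 --seed 7 --out cohort.csv
Rscript inst/cli/airwayct.R stats --cohort cohort.csv --out tables/
```

## Documentation

The methods vignette (`vignettes/airwayct-methods.Rmd`) describes the
measurement model, its assumptions and numerical choices, what the
phantoms and the synthetic cohort do and do not emulate, and known
limitations.
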