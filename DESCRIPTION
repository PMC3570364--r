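Package: airwayct
Title: Airway Wall Thickness and Emphysema Quantification on Low-Dose Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies airway wall thickness at a fixed internal lumen
    diameter (default 3.5 mm) from chest CT volumes by perpendicular
    cross-sectional resampling, half-maximum inner border detection and
    partial-volume-robust Hounsfield-unit integration across the wall,
    with assessed-perimeter-fraction (APF) weighting across lung lobes.
    Also provides trachea-recalibrated lung densitometry (Perc15,
    percentage of low-attenuation area below -950 HU, lung volume),
    digital CT phantoms of airway trees with ground truth, a synthetic
    heavy-smoker cohort generator, an APF-maximizing diameter sweep, and
    the statistical layer (descriptives, rank tests, univariate and
    multivariate least squares with variance partitioning, Bland-Altman
    agreement) linking airway wall thickness and emphysema to airflow
    limitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
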