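---
title: "Quantitative histology of radial plant-organ cross-sections: methods"
author: "quanthisto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative histology of radial plant-organ cross-sections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quanthisto)
```

# The problem

Secondary growth thickens stems and roots radially: a cylindrical stem-cell
layer, the vascular cambium, produces xylem towards the organ center and
phloem towards the periphery. In the Arabidopsis hypocotyl this process takes
a section from a few hundred cells to tens of thousands within weeks, and it
can only be observed invasively, one fixed cross-section per individual.
Quantifying it therefore requires automation: segment every cell in a
high-resolution section image, describe each cell numerically, recognize its
tissue type, and summarize sections into comparable statistics.

`quanthisto` implements that pipeline — segmentation, 16-component cell
descriptors, SVM cell-type recognition with greedy feature selection,
mask-based quality control, phenoprints with correlation PCA, incline-angle
morphodynamics, and Bayesian phloem-pole periodicity — together with a
synthetic-section generator that makes every stage testable without image
downloads.

# The synthetic-section generator

`section_spec()` / `generate_section()` emulate the radial anatomy of a
hypocotyl cross-section as concentric zones of "brick" cells: annular bands
subdivided into arcs, with jittered band edges and arc widths. Walls are
rasterized dark (toluidine-blue bright-field appearance, walls ~60/255 on a
~200/255 lumen), Gaussian intensity noise is added, and the ground truth
(label map, per-cell class, analytic centroid/axis/area) is returned along
with filled section and xylem masks.

The default geometry portrays a mid-stage section:

* zone radii 250 / 280 / 480 µm (xylem / cambium / phloem outer),
  0.35 µm/px — a ~3000 px image with roughly a thousand cells;
* xylem: an inner vessel/parenchyma zone (mean cell 900 µm²) and an outer
  fiber zone (450 µm²), both radially elongated (incline near π/2);
* cambium: a thin ring of small (200 µm²), strongly orthoradial cells;
* phloem: large orthoradial parenchyma (1300 µm²) with clusters of small
  bundle cells (250 µm²) at poles spaced every ~140 µm of cambial arc
  (count = ⌊2πR/s⌋, equal angular spacing);
* `generate_gus_ring()` renders the same pole geometry as dark staining foci
  on a bright background for the periodicity analysis.

Cell sizes were chosen once so that tissue proportions, within-zone
elongation and total cell count are of the order reported for mid-stage
hypocotyls; they are parameters, not fitted values. What the generator does
**not** emulate: irregular cell outlines, wall-thickness variation, staining
gradients, sectioning artifacts, or growth through time (each time point is
an independent spec). Passing tests on synthetic sections therefore
demonstrate the correctness of the algorithms under controlled geometry, not
performance on real micrographs.

A deliberate consequence of the analytic construction is that *aggregate*
statistics (zone areas, cell counts, class proportions) are nearly identical
across random seeds of the same spec; distinct biological conditions are
modeled as distinct specs, e.g. growing zone radii across time points.

# Segmentation

Images are optionally assembled from 1024×1024 tiles (`tile_image()` /
`stitch_tiles()`, exact row-major abutment, bit-exact round trip), then:

1. `preprocess()` — gamma, then contrast, then brightness on the normalized
   intensity scale; identity by default.
2. `binarize_adaptive()` — a pixel is wall iff it is darker than the local
   Gaussian-weighted mean minus an offset (default window 31 px, offset 10).
   Adaptive thresholding makes the wall network robust to illumination
   gradients; on the synthetic noise model (sd 8) it leaves ~10% salt
   speckle in the background, which the next step removes.
3. `morph_clean()` — erosions followed by dilations with a disc element.
   The operation counts are exposed; the pipeline default is one erosion and
   one dilation (an opening), which removes isolated noise pixels while
   preserving 3–5 px walls. Two erosions (also supported) require thicker
   walls than the generator draws.
4. `watershed_segment()` — seeds are the local maxima of the distance
   transform of the non-wall region; the watershed floods the inverted
   distance transform; objects below 20 px² are discarded. The merge
   `tolerance` (default 2) absorbs the ±1–2 px distance-ridge fluctuation
   that wall-edge noise induces in elongated cells; because intact walls
   carry distance ~0, neighbouring lumina can only merge through actual wall
   breaks, so moderate tolerance does not cause under-segmentation.

`segmentation_error_rate()` scores a prediction against ground truth: a true
cell is mis-segmented when no predicted label overlaps it with IoU ≥ 0.5,
which catches merges, splits and misses with one threshold. On default
synthetic sections the pipeline mis-segments well under 1% of cells.

# Cell descriptors

`build_feature_table()` computes 16 descriptors per cell — 10 geometric and
6 positional:

* moments ellipse: the central second-moment matrix is eigen-decomposed
  (equivalent to fitting an ellipse); axes are 4√λ, the orientation is the
  leading eigenvector's angle in [−π/2, π/2). Single-pixel cells are
  degenerate and flagged.
* area (pixel count · px²), perimeter (8-connected Moore contour tracing;
  axial steps count 1, diagonal √2), and the mean/sd/min/max of
  centroid-to-boundary-pixel distances.
* polar position relative to the manually defined (here: construction)
  center: radius in µm, radius normalized so that the average distance of
  the outermost cells (those above the 0.95 radius quantile) maps to 1.0,
  and the polar angle.
* the incline angle θ = |arccos(x·r/(‖x‖‖r‖)) − π/2| between the major-axis
  vector x and the radius vector r: 0 = orthoradial (periclinal), π/2 =
  radial (anticlinal). θ is invariant to the sign and scale of both vectors.

All pixel coordinates are 1-based (row = y, col = x, origin top-left);
centers and centroids are stored as (x, y).

The exact descriptor inventory is this package's fixed choice: the moment
ellipse family plus boundary-radius statistics on the geometric side and the
polar/incline family on the positional side. The boundary-radius standard
deviation ("radius variability") is the one descriptor whose tissue
dependence makes it a frequent exclusion candidate during feature selection.

# Cell-type recognition

Five classes are recognized: xylem vessel/parenchyma, xylem fiber, cambium,
phloem bundle, phloem parenchyma (`cell_classes()`).

* `split_training()` — stratified 2/3 learning, 1/3 test split, seeded.
* `crossval_svm()` — V (default 5) randomly permuted reiterations of
  stratified train/test splits; per fold, features are z-scored with
  parameters from the training portion only, an RBF-kernel C-classification
  SVM is fitted, and held-out accuracy recorded. Zero-variance features are
  dropped with a warning.
* `greedy_feature_selection()` — forward selection over the 16 descriptors:
  at step k the feature maximizing CV mean accuracy given the k−1 chosen is
  added (ties resolved by fixed feature order). The recommended set is the
  smallest within 0.5 percentage points of the best mean accuracy, with the
  lowest accuracy sd as tie-break — fewest descriptors, lowest variation,
  highest performance.
* `train_classifier()` — small log-grid search (C ∈ {1,10,100},
  γ ∈ {0.1,1,10}/d) by the same CV, final fit on all training rows; the
  z-scoring parameters, hyperparameters and CV record are stored with the
  model, and `save_classifier()`/`load_classifier()` persist it as a params
  JSON plus model blob. One classifier is intended per genotype × time
  point, keyed `genotype_timepoint` in the pipeline registry.

On synthetic sections the classes are separable mainly by position and size,
and a classifier trained on two labeled sections scores well above the 88%
working threshold on a held-out section. Real tissue is harder; the greedy
selection and per-time-point classifiers are the mechanisms that absorb that
difficulty, not the synthetic benchmark.

# Quality control

`filter_outside()` drops objects whose centroid falls outside the
whole-section mask (dirt, shed cortex cells, mis-segmented debris).
`correct_xylem()` repairs the characteristic vessel-versus-phloem-parenchyma
confusion using the xylem-area mask. The default policy is bidirectional —
xylem-classed cells outside the mask become phloem parenchyma, phloem
parenchyma inside becomes xylem vessel/parenchyma — because the confusion is
symmetric in feature space; a one-directional policy is available
(`direction = "to_phloem"` / `"to_xylem"`). Membership is tested at the
rounded centroid pixel for speed. The correction is idempotent, preserves
the row count, and guarantees the post-state that no xylem-classed centroid
lies outside the xylem mask.

# Phenoprints and PCA

`compute_phenoprint()` reduces one genotype × time point to 8 numbers:
median total cell count, median total transverse area, the five class
proportions (per-section proportions, medians across sections, renormalized
to sum exactly 1), and the median incline. The composition is recorded in
the object; alternates can be swapped in by constructing the matrix
directly. `normalize_unit_range()` divides each variable by its maximum over
the samples (unit range), and `pca_correlation()` eigen-decomposes the
correlation matrix — eigenvalues sum to the variable count, scores are the
standardized data on the eigenvectors (score variance with the n−1
denominator equals the eigenvalue), and each loading's sign is fixed so its
largest-magnitude entry is positive, making biplots reproducible.

# Incline morphodynamics

* `dip_test()` — Hartigans' dip statistic, computed with the iterative
  greatest-convex-minorant / least-concave-majorant algorithm in rank units
  (final value = count discrepancy / 2n). The implementation is validated in
  the test suite against an independent linear-programming oracle that
  minimizes the sup-distance to a unimodal CDF directly from the definition.
  P-values come from a seeded uniform-null bootstrap (default 2000
  replicates) rather than interpolation tables; the uniform is the
  asymptotically least favourable unimodal null and the dip is
  location-scale invariant.
* `lowess_trend()` — locally weighted linear regression (3 robustifying
  iterations) of incline against normalized radius, evaluated on a 200-point
  grid. The span default 0.3 is this package's choice, exposed and recorded
  in outputs.
* `radial_class_profile()` — per-class incline quartiles (type-7 linear
  interpolation), 1.5·IQR outliers, box placed at the class's mean radial
  position.
* `incline_density()` — Gaussian kernel density with reflection at 0 and
  π/2, renormalized to integrate to 1 (violin-plot backbone).
* `count_within_radius()` — cell counts in fixed pixel radii around the
  center.

Pooling is per time point across sections (the per-section option is a
matter of passing one table); bimodality of the pooled incline distribution
is the signature of established radial/orthoradial tissue organization.

# Phloem-pole periodicity

`kde_map()` renders a Gaussian kernel density of predicted bundle-cell
positions (poles appear as density peaks). For precise spacing estimation,
`ring_profile()` measures blurred intensity along a circular ROI concentric
with the section center (intensity inverted so dark staining foci become
peaks), and `bayesian_period()` performs single-sinusoid Bayesian spectral
estimation: for each candidate arc period the linear model
a + b·cos + c·sin is scored by its marginal likelihood with coefficients
integrated out under flat priors and the noise scale under Jeffreys' prior
(Student-t form |X′X|^(−1/2)·RSS^(−(N\*−3)/2)), a flat prior over the period
range, and trapezoid normalization on the grid.

Two numerical choices matter. First, ring profiles are oversampled (one
sample per pixel of arc) and blurred, so residuals are autocorrelated; the
exponent uses an effective sample size N\* = N(1−ρ)/(1+ρ) from the lag-1
autocorrelation of the best-fit residuals. This keeps the posterior honest:
constant spacing yields a posterior concentrating >80% of its mass within
±10% of the MAP, while spacings jittered by 30% — a "stochastic" pole
placement — spread the posterior below 50% concentration, which is the
package's operational test of patterned versus random pole positioning.
Second, the circular signal is handled by periodic sampling (the profile
wraps); a flat profile returns a near-uniform posterior flagged
`dominant = FALSE`. `arc_spacing_um()` converts the MAP period to physical
spacing.

# Pipeline and determinism

`run_pipeline()` executes generate/stitch → preprocess → binarize → clean →
watershed → features → classify → QC → phenoprint/morphodynamics/poles into
a write-once run directory (`images/`, `labels/`, `tables/`, `models/`,
`reports/`, `config.resolved.yaml`, `run.log` with per-stage lines and MD5
checksums). Any stage failure aborts with the stage name; a classification
request without a trained classifier or registry entry for a
genotype × time point key fails naming the key. All randomness flows from
the config seed through `local_seed()`, so a rerun with the same config is
bit-identical in its feature tables. The `exec/quanthisto` script exposes
the same stages as shell subcommands.

# Problem sizes and limitations

The shipped tests exercise three section scales: tiny (110 µm radius at
1 µm/px, ~115 cells) for structural checks, mid (240 µm at 0.7 µm/px,
~290 cells) for accuracy checks, and the full default (480 µm at 0.35 µm/px,
~1100 cells in a ~3000 px frame) for the end-to-end segmentation benchmark;
bootstrap sizes in tests are a few hundred where the default would be 2000.
These sizes were chosen to keep the suite comfortably interactive while
leaving every quantitative claim intact at the defaults.

Known limitations: the descriptor set omits wall-thickness and
cell-connectivity features; the classifier benchmark inherits the synthetic
geometry's strong position/size separability; grayscale (non-binary)
watershed — more accurate but slower — is not the default path; and
real-data summaries (e.g. published PCA variance fractions) depend on the
original per-cell tables and are outside what the synthetic conditions can
or should reproduce.
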