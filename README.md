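# quanthisto

Automated quantitative histology for transverse sections of radially
organized plant organs — the Arabidopsis hypocotyl during secondary growth
being the motivating case. Secondary growth is driven by the vascular
cambium, a cylindrical stem-cell layer that deposits xylem inward and phloem
outward; following it at cellular resolution means segmenting thousands of
cells per cross-section, recognizing their tissue type, and summarizing
whole sections into comparable statistics. `quanthisto` implements that
pipeline end to end, for image data or for its own synthetic sections.

## What it computes

* **Segmentation** — stitching of 1024×1024 image tiles, preprocessing
  (gamma/contrast/brightness), adaptive Gaussian-mean binarization of the
  dark cell-wall network, morphological clean-up, and watershed segmentation
  with automatic seeding from the distance transform. Accuracy is scored
  against ground truth with an IoU ≥ 0.5 one-to-one criterion.
* **Cell descriptors** — a 16-component vector per cell: moments-ellipse
  geometry (axes, orientation, eccentricity, equivalent to fitting an
  ellipse from the 2nd-order covariance of the pixel set), area, contour
  perimeter, boundary-radius statistics, and polar position including the
  *incline angle*

  θ = |arccos( x·r / (‖x‖‖r‖) ) − π/2|,

  the deviation of the cell's major axis **x** from the section radius
  **r** through its centroid: θ = 0 for orthoradial (periclinal) cells,
  θ = π/2 for radial (anticlinal) ones.
* **Cell-type recognition** — RBF-kernel C-classification SVMs over five
  categories (xylem vessel/parenchyma, xylem fiber, cambium, phloem bundle,
  phloem parenchyma), with stratified 2/3–1/3 splitting, V-fold permuted
  cross-validation, and greedy forward feature selection.
* **Quality control** — mask-based filtering of objects outside the section
  and automatic correction of the xylem-versus-phloem-parenchyma confusion
  against the xylem-area mask.
* **Tissue-level analyses** — 8-component phenoprints with unit-range
  normalization and correlation-matrix PCA; incline morphodynamics
  (Hartigans' dip test of bimodality with bootstrap p-values, lowess radial
  trends, per-class radial profiles, violin densities); and phloem-pole
  periodicity (kernel density maps, circular-ROI intensity profiles, and a
  single-sinusoid Bayesian posterior over the arc period between poles).
* **Synthetic sections** — `generate_section()` builds seeded, ground-truthed
  images of concentric xylem/cambium/phloem zones with equidistant phloem
  poles, so the whole pipeline is testable without external data.

## Worked example

```r
library(quanthisto)

# a mid-size synthetic section: 240 um radius at 0.7 um/px
spec <- section_spec(
  zone_radii = c(xylem_outer = 125, cambium_outer = 140, phloem_outer = 240),
  pixel_size = 0.7, seed = 11
)
sec <- generate_section(spec)
sec$truth$label_map
#> label_map: 773 x 773 px, 292 cells

# segment it and score against the ground truth
walls  <- morph_clean(binarize_adaptive(sec$image, 31, 10), 1, 1, 3)
labels <- watershed_segment(sec$image, walls)
segmentation_error_rate(labels, sec$truth)
#> [1] 0          # every one of the 292 cells recovered one-to-one

# 16 descriptors per cell
ft <- build_feature_table(labels, sec$image$center, sec$image$pixel_size)
median(ft$incline[ft$polar_radius_norm < 0.5])   # xylem zone: radial cells
#> [1] 1.57      # close to pi/2

# is the pooled incline distribution bimodal (radial + orthoradial tissue)?
dip_test(ft$incline, n_boot = 500, seed = 1)$p_value
#> [1] 0.002     # yes: organized vascular pattern

# phloem-pole spacing from a reporter-stained ring image
gspec <- section_spec(
  zone_radii = c(xylem_outer = 240, cambium_outer = 267, phloem_outer = 460),
  pixel_size = 2.26, n_pole = 12, seed = 9
)
ring <- generate_gus_ring(gspec, background_sd = 10)
prof <- ring_profile(ring, radius = 267 / 2.26, width = 5, blur_sigma = 2)
bayesian_period(prof, period_range = c(20, 150))
#> period_posterior: MAP 62.0 px (95% CI 26.5-143.5), concentration 0.55
arc_spacing_um(62, 2.26)
#> [1] 140.12    # ~140 um between adjacent phloem poles
```

The interpretation: the section segments cleanly at this resolution, the
xylem zone is radially oriented while cambium and phloem are orthoradial
(hence the bimodal incline distribution), and the posterior over the arc
period finds one dominant spacing — poles are laid down at a constant arc
interval, a patterned rather than stochastic process.

A shell front-end wrapping the same stages is installed as
`exec/quanthisto` (subcommands `run`, `simulate`, `segment`, `features`,
`qc`, `morpho`, `poles`).

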