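# Shared synthetic fixtures, built once per test run and cached.
qh_cache <- new.env(parent = emptyenv())

# tiny section: fast, used for structural checks
tiny_spec <- function(seed = 7, ...) {
  section_spec(
    zone_radii = c(xylem_outer = 60, cambium_outer = 72, phloem_outer = 110),
    pixel_size = 1, seed = seed, ...
  )
}

# mid-size section: resolution high enough for accurate segmentation
mid_spec <- function(seed = 11, ...) {
  section_spec(
    zone_radii = c(xylem_outer = 125, cambium_outer = 140, phloem_outer = 240),
    pixel_size = 0.7, seed = seed, ...
  )
}

mid_section <- function() {
  if (is.null(qh_cache$mid)) qh_cache$mid <- generate_section(mid_spec())
  qh_cache$mid
}

mid_labels <- function() {
  if (is.null(qh_cache$mid_labels)) {
    sec <- mid_section()
    wall <- morph_clean(binarize_adaptive(sec$image, 31, 10), 1, 1, 3)
    qh_cache$mid_labels <- watershed_segment(sec$image, wall)
  }
  qh_cache$mid_labels
}

mid_features <- function() {
  if (is.null(qh_cache$mid_features)) {
    sec <- mid_section()
    qh_cache$mid_features <- build_feature_table(
      mid_labels(), sec$image$center, sec$image$pixel_size
    )
  }
  qh_cache$mid_features
}

# feature table of a section taken directly from ground truth (analytic
# geometry + class labels), bypassing segmentation
truth_table <- function(sec) {
  g <- sec$truth$cell_geometry
  ctr <- sec$truth$center
  px <- sec$truth$pixel_size
  r_um <- sqrt((g$cx - ctr[1])^2 + (g$cy - ctr[2])^2) * px
  mr <- section_mean_radius(r_um)
  inc <- mapply(function(mx, my, dx, dy) {
    incline_angle(c(mx, my), c(dx, dy))
  }, g$major_x, g$major_y, g$cx - ctr[1], g$cy - ctr[2])
  data.frame(
    cell_id = g$cell_id, class = g$class, area = g$area_um2,
    centroid_x = g$cx, centroid_y = g$cy,
    polar_radius = r_um, polar_radius_norm = r_um / mr,
    incline = inc
  )
}

# labeled feature table: segmented features + ground-truth class at centroid
labeled_features <- function(ft, sec) {
  lab <- sec$truth$label_map$labels
  xi <- pmin(pmax(as.integer(round(ft$centroid_x)), 1L), ncol(lab))
  yi <- pmin(pmax(as.integer(round(ft$centroid_y)), 1L), nrow(lab))
  tid <- lab[cbind(yi, xi)]
  cls <- rep(NA_character_, nrow(ft))
  cls[tid > 0] <- unname(sec$truth$cell_classes[as.character(tid[tid > 0])])
  out <- ft[!is.na(cls), , drop = FALSE]
  out$class <- cls[!is.na(cls)]
  out
}

# separable 5-class synthetic feature set for classifier tests
blob_data <- function(n_per_class = 30, sep = 10, seed = 5, n_noise = 2) {
  set.seed(seed)
  classes <- cell_classes()
  df <- do.call(rbind, lapply(seq_along(classes), function(i) {
    data.frame(
      class = classes[i],
      f1 = rnorm(n_per_class, i * sep),
      f2 = rnorm(n_per_class, -i * sep)
    )
  }))
  for (k in seq_len(n_noise)) df[[paste0("noise", k)]] <- rnorm(nrow(df))
  df
}
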