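# rasterize helper: label map with one cell from a pixel predicate
one_cell_map <- function(n, pred) {
  m <- matrix(0L, n, n)
  xs <- rep(1:n, each = n)
  ys <- rep(1:n, n)
  sel <- pred(xs, ys)
  m[cbind(ys[sel], xs[sel])] <- 1L
  label_map(m)
}

test_that("moment ellipse matches analytic rectangle moments", {
  # axis-aligned 12x4 rectangle: orientation 0, axis ratio equal to the
  # closed-form moment ratio of the discrete rectangle (variance (w^2-1)/12)
  lm <- one_cell_map(24, function(x, y) x >= 5 & x <= 16 & y >= 9 & y <= 12)
  e <- ellipse_from_moments(lm, 1)
  expect_equal(e$orientation, 0)
  expect_equal(
    e$major_axis / e$minor_axis,
    sqrt((12^2 - 1) / (4^2 - 1))
  )
  expect_equal(e$major_axis, 4 * sqrt((12^2 - 1) / 12))
  expect_equal(unname(e$centroid), c(10.5, 10.5))

  # continuous-limit check: ratio close to w/h
  expect_lt(abs(e$major_axis / e$minor_axis - 3), 0.12)

  # the same rectangle rotated 30 degrees: orientation recovered
  th <- 30 * pi / 180
  lm30 <- one_cell_map(40, function(x, y) {
    u <- (x - 20) * cos(th) + (y - 20) * sin(th)
    v <- -(x - 20) * sin(th) + (y - 20) * cos(th)
    abs(u) <= 8 & abs(v) <= 2.5
  })
  e30 <- ellipse_from_moments(lm30, 1)
  expect_lt(abs(e30$orientation - th), 0.02)

  # solid disc: eccentricity ~ 0
  disc <- one_cell_map(41, function(x, y) (x - 21)^2 + (y - 21)^2 <= 15^2)
  ed <- ellipse_from_moments(disc, 1)
  expect_lt(ed$eccentricity, 0.05)
  expect_lt(abs(ed$major_axis / ed$minor_axis - 1), 0.02)

  # single-pixel cell: degenerate, flagged
  px1 <- one_cell_map(5, function(x, y) x == 3 & y == 3)
  e1 <- ellipse_from_moments(px1, 1)
  expect_true(e1$degenerate)
  expect_identical(e1$minor_axis, 0)
  expect_identical(e1$eccentricity, 1)
})

test_that("shape statistics match brute-force boundary enumeration", {
  # 10x10 square at 1 um/px: area 100 um2; contour tracing walks 4 x 9 steps
  sq <- one_cell_map(14, function(x, y) x >= 3 & x <= 12 & y >= 3 & y <= 12)
  s <- shape_stats(sq, 1, pixel_size = 1)
  expect_identical(s$area, 100)
  expect_identical(s$perimeter, 36)
  # pixel_size scales area quadratically, lengths linearly
  s2 <- shape_stats(sq, 1, pixel_size = 0.5)
  expect_identical(s2$area, 25)
  expect_identical(s2$perimeter, 18)

  # disc of radius R: boundary radii concentrate at R
  disc <- one_cell_map(41, function(x, y) (x - 21)^2 + (y - 21)^2 <= 15^2)
  sd_ <- shape_stats(disc, 1, 1)
  expect_lt(abs(sd_$radius_mean - 15), 0.5)
  expect_lt(sd_$radius_sd, 0.5)

  # L-shaped cell: radii stats equal brute-force enumeration over its
  # boundary pixels (4-neighbour criterion)
  lmap <- one_cell_map(20, function(x, y) {
    (x >= 3 & x <= 12 & y >= 3 & y <= 6) | (x >= 3 & x <= 6 & y >= 3 & y <= 14)
  })
  sl <- shape_stats(lmap, 1, 1)
  idx <- which(lmap$labels == 1L)
  ys <- (idx - 1) %% 20 + 1
  xs <- (idx - 1) %/% 20 + 1
  cx <- mean(xs)
  cy <- mean(ys)
  inside <- function(x, y) {
    x >= 1 && x <= 20 && y >= 1 && y <= 20 && lmap$labels[y, x] == 1L
  }
  on_boundary <- mapply(function(x, y) {
    !(inside(x - 1, y) && inside(x + 1, y) && inside(x, y - 1) && inside(x, y + 1))
  }, xs, ys)
  r <- sqrt((xs[on_boundary] - cx)^2 + (ys[on_boundary] - cy)^2)
  expect_equal(sl$radius_mean, mean(r))
  expect_equal(sl$radius_sd, sd(r))
  expect_equal(sl$radius_min, min(r))
  expect_equal(sl$radius_max, max(r))
})

test_that("polar positions follow the 3-4-5 geometry and normalization", {
  p <- polar_position(c(4, 5), center = c(1, 1), section_mean_radius = 10, pixel_size = 1)
  expect_equal(p$polar_radius, 5)
  expect_equal(p$polar_radius_norm, 0.5)
  expect_equal(p$polar_angle, atan2(4, 3))
  # cell at the center
  p0 <- polar_position(c(7, 7), c(7, 7), 10, 1)
  expect_identical(p0$polar_radius, 0)
  expect_identical(p0$polar_radius_norm, 0)
  expect_error(polar_position(c(1, 1), NULL, 10), "center")
  expect_error(polar_position(c(1, 1), c(0, 0), 0), "section_mean_radius")

  # outermost cells average to normalized radius 1 by construction
  radii <- c(runif(50, 0, 80), rep(100, 5))
  mr <- section_mean_radius(radii, 0.95)
  expect_equal(mr, 100)
})

test_that("incline angle hits its analytic limits and symmetries", {
  expect_equal(incline_angle(c(1, 1), c(2, 2)), pi / 2) # parallel: radial
  expect_equal(incline_angle(c(0, 1), c(1, 0)), 0) # perpendicular: orthoradial
  expect_equal(incline_angle(c(1, 0), c(1, 1)), pi / 4) # 45 degrees
  expect_error(incline_angle(c(0, 0), c(1, 0)), "non-zero")

  # symmetry / scale invariance property
  set.seed(1)
  for (i in 1:50) {
    x <- rnorm(2)
    r <- rnorm(2)
    if (sum(x^2) == 0 || sum(r^2) == 0) next
    a <- incline_angle(x, r)
    expect_equal(incline_angle(-x, r), a)
    expect_equal(incline_angle(3.7 * x, 0.2 * r), a)
    expect_true(a >= 0 && a <= pi / 2)
  }
})

test_that("feature tables carry 16 descriptors and are reproducible", {
  sec <- mid_section()
  ft <- mid_features()
  expect_s3_class(ft, "feature_table")
  expect_identical(names(ft), c("cell_id", descriptor_names()))
  expect_length(descriptor_names(), 16)
  expect_identical(ft$cell_id, seq_len(nrow(ft)))
  expect_true(all(ft$area > 0))
  expect_true(all(ft$minor_axis <= ft$major_axis))
  expect_true(all(ft$eccentricity >= 0 & ft$eccentricity <= 1))
  expect_true(all(ft$incline >= 0 & ft$incline <= pi / 2))

  # bit-identical recomputation
  ft2 <- build_feature_table(mid_labels(), sec$image$center, sec$image$pixel_size)
  expect_identical(as.data.frame(ft), as.data.frame(ft2))

  # empty label map -> empty table with full header
  e <- build_feature_table(label_map(matrix(0L, 5, 5)), c(3, 3), 1)
  expect_identical(nrow(e), 0L)
  expect_identical(names(e), c("cell_id", descriptor_names()))

  # CSV round trip is lossless
  p <- tempfile(fileext = ".csv")
  write_feature_table(ft, p)
  back <- read_feature_table(p)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12)
  expect_equal(attr(back, "pixel_size"), attr(ft, "pixel_size"))
})

test_that("per-zone median incline of segmented sections matches construction", {
  sec <- mid_section()
  ft <- labeled_features(mid_features(), sec)
  xyl <- ft$incline[ft$class %in% c("xylem_vessel_parenchyma", "xylem_fiber")]
  oth <- ft$incline[ft$class %in% c("cambium", "phloem_parenchyma")]
  expect_gt(median(xyl), pi / 4)
  expect_lt(median(oth), pi / 4)
})

test_that("moment ellipse area approximates pixel area for convex cells", {
  ft <- mid_features()
  # brick-like cells away from the centre wedges
  sel <- ft$polar_radius_norm > 0.3 & ft$polar_radius_norm < 0.95
  ratio <- (pi * ft$major_axis[sel] / 2 * ft$minor_axis[sel] / 2) / ft$area[sel]
  expect_gt(mean(abs(ratio - 1) < 0.15), 0.9)
  expect_lt(abs(median(ratio) - 1), 0.1)
})
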