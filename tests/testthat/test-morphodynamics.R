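test_that("dip statistic matches known closed-form cases", {
  # a two-point sample is fit best by a uniform CDF at distance 1/4
  expect_equal(dip_stat(c(0, 1)), 0.25)
  # evenly spaced samples attain the lower bound 1/(2n)
  expect_equal(dip_stat(1:10), 1 / 20)
  expect_equal(dip_stat(seq(0, 1, length.out = 25)), 1 / 50)
  # constant sample: dip 0
  expect_identical(dip_stat(rep(3, 8)), 0)
  # order invariance
  set.seed(2)
  x <- rnorm(40)
  expect_equal(dip_stat(sample(x)), dip_stat(x))
  # affine invariance
  expect_equal(dip_stat(5 - 2 * x), dip_stat(x))
})

test_that("dip statistic equals exhaustive unimodal-fit optimization", {
  # LP oracle: minimal sup-distance to a unimodal CDF, from the definition
  # (helper-dip-oracle.R); exact on well-separated samples
  hand6 <- c(0.1, 0.22, 0.3, 0.7, 0.81, 0.9) # bimodal 6-point hand sample
  expect_equal(dip_stat(hand6), dip_lp(hand6), tolerance = 1e-9)

  set.seed(14)
  tested <- 0
  while (tested < 25) {
    n <- sample(4:10, 1)
    x <- sort(switch(sample(3, 1),
      runif(n),
      c(runif(ceiling(n / 2), 0, 0.2), runif(floor(n / 2), 0.8, 1)),
      rnorm(n)
    ))
    if (min(diff(x)) < 0.02 * diff(range(x))) next # LP conditioning domain
    tested <- tested + 1
    expect_equal(dip_stat(x), dip_lp(x), tolerance = 1e-7)
  }
})

test_that("dip test separates uniform from strongly bimodal samples", {
  set.seed(5)
  u <- runif(1000)
  r <- dip_test(u, n_boot = 300, seed = 17)
  expect_gt(r$p_value, 0.001)

  bim <- c(rnorm(500, 0), rnorm(500, 6))
  rb <- dip_test(bim, n_boot = 1200, seed = 17)
  expect_lt(rb$p_value, 0.001)

  # constant sample: dip 0, p 1
  rc <- dip_test(rep(1, 20))
  expect_identical(rc$dip, 0)
  expect_identical(rc$p_value, 1)
  expect_error(dip_test(1:5), "at least 10")
})

test_that("dip p-values are approximately uniform under the uniform null", {
  set.seed(23)
  reps <- 200
  pvals <- vapply(seq_len(reps), function(i) {
    dip_test(runif(50), n_boot = 120, seed = 1000 + i)$p_value
  }, numeric(1))
  # KS distance to uniform below the 1% critical value scale
  grid <- seq(0, 1, by = 0.01)
  ks <- max(abs(vapply(grid, function(g) mean(pvals <= g), numeric(1)) - grid))
  expect_lt(ks, 0.15)
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.62)
})

test_that("pooled incline of a patterned section is bimodal, single-orientation is not", {
  sec <- mid_section()
  ft <- labeled_features(mid_features(), sec)
  # mixed zones -> bimodal (radial xylem near pi/2, orthoradial rest near 0)
  r <- dip_test(ft$incline, n_boot = 500, seed = 3)
  expect_lt(r$p_value, 0.01)
  # a single-orientation population: only the phloem parenchyma cells
  one <- ft$incline[ft$class == "phloem_parenchyma"]
  r1 <- dip_test(one, n_boot = 500, seed = 3)
  expect_gt(r1$p_value, 0.05)
})

test_that("lowess trends reproduce lines and constructed plateau profiles", {
  # constant incline: flat line at that value
  flat <- lowess_trend(runif(100), rep(0.7, 100), frac = 0.3)
  expect_true(all(abs(flat$incline - 0.7) < 1e-9))
  # noiseless linear relation recovered at interior grid points
  x <- seq(0, 1, length.out = 200)
  lin <- lowess_trend(x, 0.2 + 0.9 * x, frac = 0.3)
  interior <- lin$radius_norm > 0.05 & lin$radius_norm < 0.95
  expect_true(all(abs(lin$incline - (0.2 + 0.9 * lin$radius_norm))[interior] < 1e-6))
  # xylem plateau near pi/2 then drop at the cambium: fitted curve decreases
  # monotonically across the constructed boundary
  set.seed(4)
  r <- runif(600)
  inc <- ifelse(r < 0.45, pi / 2 - 0.05, 0.1) + rnorm(600, 0, 0.02)
  tr <- lowess_trend(r, inc, frac = 0.3)
  win <- tr$radius_norm >= 0.3 & tr$radius_norm <= 0.65
  expect_true(all(diff(tr$incline[win]) <= 1e-9))
  expect_gt(tr$incline[which.min(abs(tr$radius_norm - 0.2))], 1.3)
  expect_lt(tr$incline[which.min(abs(tr$radius_norm - 0.8))], 0.3)

  expect_error(lowess_trend(r, inc, frac = 0), "frac")
  expect_error(lowess_trend(1:5, 1:5), "20")
})

test_that("per-class radial profiles use type-7 quartiles at mean class radius", {
  tab <- data.frame(
    class = "cambium", incline = c(1:9) / 10,
    polar_radius_norm = seq(0.5, 0.6, length.out = 9)
  )
  pr <- radial_class_profile(tab)
  expect_equal(pr$q1, 0.3)
  expect_equal(pr$q2, 0.5)
  expect_equal(pr$q3, 0.7)
  expect_equal(pr$mean_radius_norm, mean(tab$polar_radius_norm))
  expect_identical(pr$n_outliers, 0L)
  # symmetric values: median equals the mean of the extremes
  expect_equal(pr$q2, (min(tab$incline) + max(tab$incline)) / 2)
  expect_identical(attr(pr, "absent"), setdiff(cell_classes(), "cambium"))

  # synthetic section: class boxes are radially ordered
  sec <- mid_section()
  prs <- radial_class_profile(truth_table(sec))
  m <- setNames(prs$mean_radius_norm, prs$class)
  expect_lt(m[["xylem_vessel_parenchyma"]], m[["xylem_fiber"]])
  expect_lt(m[["xylem_fiber"]], m[["cambium"]])
  expect_gt(m[["phloem_parenchyma"]], m[["cambium"]])
  expect_gt(m[["phloem_parenchyma"]], m[["phloem_bundle"]])
})

test_that("cell counts within fixed radii are monotone and exact", {
  tab <- data.frame(
    cell_id = 1:12,
    centroid_x = c(rep(100, 7), rep(400, 5)),
    centroid_y = 100
  )
  attr(tab, "center") <- c(x = 100, y = 100)
  ct <- count_within_radius(tab, c(0, 200, 299, 300))
  expect_identical(ct$n_cells, c(7L, 7L, 7L, 12L)) # 7 at the centre, 5 at d=300
  expect_true(all(diff(ct$n_cells) >= 0))
  expect_error(count_within_radius(tab, -5), "non-negative")
  sec <- mid_section()
  counts <- count_within_radius(mid_features(), c(100, 150, 200, 250))
  expect_true(all(diff(counts$n_cells) >= 0))
})

test_that("incline densities integrate to one and find both modes", {
  d <- incline_density(runif(200, 0, pi / 2))
  dx <- diff(d$incline[1:2])
  expect_equal(sum((d$density[-1] + d$density[-nrow(d)]) / 2) * dx, 1,
    tolerance = 1e-6
  )
  # two interior clusters produce two local maxima at the cluster centres
  set.seed(12)
  two <- incline_density(c(rnorm(300, 0.4, 0.05), rnorm(300, 1.2, 0.05)))
  y <- two$density
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  modes <- two$incline[peaks[order(y[peaks], decreasing = TRUE)][1:2]]
  expect_lt(abs(sort(modes)[1] - 0.4), 0.07)
  expect_lt(abs(sort(modes)[2] - 1.2), 0.07)
  # degenerate point mass: mode at the point
  pm <- incline_density(rep(pi / 4, 50))
  expect_lt(abs(pm$incline[which.max(pm$density)] - pi / 4), 0.02)
})
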