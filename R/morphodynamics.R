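#' Lowess trend of incline versus radial position
#'
#' Fits a locally weighted linear regression (lowess, 3 robustifying
#' iterations) to the cloud of per-cell (normalized radius, incline) points
#' and evaluates it on a regular radius grid — the red trend curves over the
#' incline density plots.
#'
#' @param radius_norm normalized radial positions.
#' @param incline incline angles (rad).
#' @param frac lowess smoother span in (0, 1].
#' @param grid_n number of grid points on `[0, 1]`.
#' @param iter robustifying iterations.
#' @return data.frame with `radius_norm`, `incline` (fitted), over the grid.
#' @export
lowess_trend <- function(radius_norm, incline, frac = 0.3, grid_n = 200L, iter = 3L) {
  .assert(length(radius_norm) == length(incline), "inputs must align")
  .assert(length(radius_norm) >= 20, "need at least 20 points")
  .assert(frac > 0 && frac <= 1, "frac must be in (0, 1]")
  fit <- stats::lowess(radius_norm, incline, f = frac, iter = iter)
  grid <- seq(0, 1, length.out = grid_n)
  data.frame(
    radius_norm = grid,
    incline = stats::approx(fit$x, fit$y, xout = grid, rule = 2, ties = mean)$y
  )
}

#' Per-class incline quartiles at the class's average radial position
#'
#' For each cell-type class: the quartiles of its incline distribution
#' (linear, type-7 interpolation), outliers by the 1.5 IQR rule, and the
#' mean normalized radial position at which the class's box is placed.
#' Classes absent from the table are omitted and noted.
#'
#' @param table classified table with `class`, `incline`,
#'   `polar_radius_norm` columns.
#' @return data.frame (one row per present class): `class`, `q0` .. `q4`
#'   (min, quartiles, max of non-outlier range), `n_outliers`,
#'   `mean_radius_norm`, `n`; attribute `absent` lists omitted classes.
#' @export
radial_class_profile <- function(table) {
  .assert(
    all(c("class", "incline", "polar_radius_norm") %in% names(table)),
    "table must have class, incline, polar_radius_norm"
  )
  present <- intersect(cell_classes(), unique(table$class))
  rows <- lapply(present, function(cl) {
    v <- table$incline[table$class == cl]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    inw <- v[v >= lo & v <= hi]
    data.frame(
      class = cl, q0 = min(inw), q1 = q[1], q2 = q[2], q3 = q[3],
      q4 = max(inw), n_outliers = sum(v < lo | v > hi),
      mean_radius_norm = mean(table$polar_radius_norm[table$class == cl]),
      n = length(v)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "absent") <- setdiff(cell_classes(), present)
  out
}

#' Count cells within fixed pixel radii of the section center
#'
#' @param table table with `centroid_x`, `centroid_y` (px).
#' @param radii_px radii in pixels (non-negative).
#' @param center `c(x, y)`; defaults to the table's `center` attribute.
#' @return data.frame with `radius_px`, `n_cells` (counts are
#'   non-decreasing in the radius).
#' @export
count_within_radius <- function(table, radii_px = c(200, 300, 400, 500),
                                center = attr(table, "center")) {
  .assert(all(radii_px >= 0), "radii must be non-negative")
  .assert(!is.null(center), "center not available")
  d <- sqrt((table$centroid_x - center[1])^2 + (table$centroid_y - center[2])^2)
  data.frame(
    radius_px = radii_px,
    n_cells = vapply(radii_px, function(r) sum(d <= r), integer(1))
  )
}

#' Boundary-reflected kernel density of incline angles
#'
#' Gaussian kernel density on the support `[0, pi/2]` with reflection at
#' both boundaries, normalized to integrate to 1 on the grid — the density
#' backbone of incline violin plots.
#'
#' @param values incline angles in `[0, pi/2]` (>= 10 values).
#' @param grid_n number of grid points.
#' @param bw bandwidth; default `stats::bw.nrd0` of the sample.
#' @return data.frame with `incline`, `density`.
#' @export
incline_density <- function(values, grid_n = 512L, bw = NULL) {
  .assert(length(values) >= 10, "need at least 10 values")
  if (is.null(bw)) bw <- stats::bw.nrd0(values)
  if (!is.finite(bw) || bw <= 0) bw <- 0.02 # degenerate (near-constant) sample
  aug <- c(values, -values, pi - values) # reflect at 0 and pi/2
  d <- stats::density(aug, bw = bw, from = 0, to = pi / 2, n = grid_n)
  y <- 3 * d$y
  dx <- diff(d$x[1:2])
  integral <- sum((y[-1] + y[-length(y)]) / 2) * dx
  data.frame(incline = d$x, density = y / integral)
}
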