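#' The 16 per-cell descriptors
#'
#' Canonical names and order of the 16-component descriptor vector: 10
#' geometric features (area, perimeter, ellipse axes/eccentricity/orientation
#' from image moments, and the mean/sd/min/max of the centroid-to-boundary
#' radius) and 6 positional features (centroid, polar radius raw and
#' normalized, polar angle, incline angle).
#'
#' @return character vector of length 16.
#' @export
descriptor_names <- function() {
  c(
    "area", "perimeter", "major_axis", "minor_axis", "eccentricity",
    "orientation", "radius_mean", "radius_sd", "radius_min", "radius_max",
    "centroid_x", "centroid_y", "polar_radius", "polar_radius_norm",
    "polar_angle", "incline"
  )
}

#' Incline angle of a cell's major axis relative to the section radius
#'
#' The incline \eqn{\theta = | \arccos( x \cdot r / (\|x\| \|r\|) ) - \pi/2 |}
#' measures the deviation of the cell's major-axis vector `x` from the radius
#' vector `r` running from the section center through the cell centroid:
#' 0 is perfectly orthoradial (tangential/periclinal) orientation, \eqn{\pi/2}
#' perfectly radial (anticlinal). The value is invariant to rescaling either
#' vector and to flipping the sign of `x` (an axis has no direction).
#'
#' @param x major-axis vector `c(x, y)` (non-zero).
#' @param r radius vector `c(x, y)` (non-zero).
#' @return incline in radians, in `[0, pi/2]`.
#' @examples
#' incline_angle(c(1, 1), c(2, 2)) # parallel: pi/2
#' incline_angle(c(0, 1), c(1, 0)) # perpendicular: 0
#' @export
incline_angle <- function(x, r) {
  nx <- sqrt(sum(x^2))
  nr <- sqrt(sum(r^2))
  .assert(nx > 0 && nr > 0, "incline_angle needs non-zero vectors")
  d <- sum(x * r) / (nx * nr)
  abs(acos(.clip(d, -1, 1)) - pi / 2)
}

#' Ellipse parameters of one cell from image moments
#'
#' Computes the central second-order moments of the cell's pixel set, whose
#' covariance eigen-decomposition is equivalent to fitting an ellipse:
#' axis lengths are `4 * sqrt(eigenvalue)`, the orientation is the angle of
#' the leading eigenvector in `[-pi/2, pi/2)`.
#'
#' @param labels a `label_map`.
#' @param cell_id label of the cell.
#' @param pixel_size µm per pixel (axes are returned in µm).
#' @return list with `major_axis`, `minor_axis`, `orientation`,
#'   `eccentricity`, `centroid` (x, y in px), `degenerate` flag (single-pixel
#'   cells return `minor_axis = 0`, `eccentricity = 1`).
#' @export
ellipse_from_moments <- function(labels, cell_id, pixel_size = 1) {
  pix <- .cell_pixels(labels, cell_id)
  m <- .moments_ellipse(pix$x, pix$y)
  list(
    major_axis = m$major * pixel_size, minor_axis = m$minor * pixel_size,
    orientation = m$orientation, eccentricity = m$eccentricity,
    centroid = c(x = m$cx, y = m$cy), degenerate = m$degenerate
  )
}

#' Shape statistics of one cell
#'
#' Area from the pixel count, perimeter from 8-connected contour tracing,
#' and summary statistics of the distances from the centroid to the boundary
#' pixels.
#'
#' @inheritParams ellipse_from_moments
#' @return list with `area`, `perimeter`, `radius_mean`, `radius_sd`,
#'   `radius_min`, `radius_max` (µm / µm²).
#' @export
shape_stats <- function(labels, cell_id, pixel_size = 1) {
  pix <- .cell_pixels(labels, cell_id)
  s <- .shape_one(pix$x, pix$y)
  list(
    area = s$area * pixel_size^2, perimeter = s$perimeter * pixel_size,
    radius_mean = s$rmean * pixel_size, radius_sd = s$rsd * pixel_size,
    radius_min = s$rmin * pixel_size, radius_max = s$rmax * pixel_size
  )
}

#' Polar position of a centroid relative to the section center
#'
#' @param centroid `c(x, y)` in px.
#' @param center `c(x, y)` in px; must be set.
#' @param section_mean_radius µm; the average distance of the outermost cells
#'   from the center, which maps to normalized radius 1.0.
#' @param pixel_size µm per pixel.
#' @return list with `polar_radius` (µm), `polar_radius_norm`,
#'   `polar_angle` (rad in `[0, 2*pi)`, counter-clockwise from +x in the
#'   image frame).
#' @export
polar_position <- function(centroid, center, section_mean_radius, pixel_size = 1) {
  .assert(!is.null(center) && length(center) == 2, "center must be set")
  .assert(section_mean_radius > 0, "section_mean_radius must be > 0")
  dx <- centroid[1] - center[1]
  dy <- centroid[2] - center[2]
  r <- sqrt(dx^2 + dy^2) * pixel_size
  list(
    polar_radius = unname(r),
    polar_radius_norm = unname(r / section_mean_radius),
    polar_angle = unname(atan2(dy, dx) %% (2 * pi))
  )
}

#' Mean radius of the outermost cells of a section
#'
#' The section's average radius is the mean centroid distance (µm) of the
#' outermost cells — those at or above the `outer_quantile` of the radius
#' distribution — from the center. Normalized polar radii are scaled so this
#' distance maps to 1.0.
#'
#' @param radii_um numeric vector of centroid distances, µm.
#' @param outer_quantile quantile defining "outermost" (default 0.95).
#' @return scalar µm.
#' @export
section_mean_radius <- function(radii_um, outer_quantile = 0.95) {
  .assert(length(radii_um) > 0, "no radii given")
  q <- stats::quantile(radii_um, outer_quantile, names = FALSE)
  mean(radii_um[radii_um >= q])
}

#' Build the 16-component feature table of a segmented section
#'
#' One row per cell, columns `cell_id` plus the 16 descriptors of
#' [descriptor_names()], ordered by `cell_id`. Geometry is computed from
#' image moments and contour tracing; positional features use the section
#' center and the section mean radius (computed from the outermost cells
#' when not supplied).
#'
#' @param labels a `label_map`.
#' @param center `c(x, y)` section center in px.
#' @param pixel_size µm per pixel.
#' @param mean_radius optional section mean radius (µm); computed via
#'   [section_mean_radius()] when `NULL`.
#' @param genotype,timepoint optional metadata stored as attributes.
#' @return `data.frame` of class `feature_table` with attributes `center`,
#'   `pixel_size`, `mean_radius`, `genotype`, `timepoint`.
#' @export
build_feature_table <- function(labels, center, pixel_size = 1,
                                mean_radius = NULL,
                                genotype = NA_character_, timepoint = NA_real_) {
  .assert(inherits(labels, "label_map"), "labels must be a label_map")
  .assert(!is.null(center) && length(center) == 2, "center must be set")
  lab <- labels$labels
  n <- labels$n_cells
  empty <- data.frame(matrix(numeric(0), 0, 17))
  names(empty) <- c("cell_id", descriptor_names())
  if (n == 0L) {
    return(.as_feature_table(empty, center, pixel_size, NA_real_, genotype, timepoint))
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  ys <- (idx - 1L) %% nrow(lab) + 1L
  xs <- (idx - 1L) %/% nrow(lab) + 1L
  ord <- order(ids)
  ids <- ids[ord]
  xs <- xs[ord]
  ys <- ys[ord]
  bounds <- c(0L, cumsum(tabulate(ids, nbins = n)))

  geo <- matrix(NA_real_, n, 16,
    dimnames = list(NULL, descriptor_names())
  )
  for (i in seq_len(n)) {
    s <- (bounds[i] + 1L):bounds[i + 1L]
    cx <- xs[s]
    cy <- ys[s]
    m <- .moments_ellipse(cx, cy)
    sh <- .shape_one(cx, cy)
    geo[i, ] <- c(
      sh$area * pixel_size^2, sh$perimeter * pixel_size,
      m$major * pixel_size, m$minor * pixel_size, m$eccentricity,
      m$orientation,
      sh$rmean * pixel_size, sh$rsd * pixel_size,
      sh$rmin * pixel_size, sh$rmax * pixel_size,
      m$cx, m$cy,
      NA, NA, NA, NA
    )
  }
  dxv <- geo[, "centroid_x"] - center[1]
  dyv <- geo[, "centroid_y"] - center[2]
  r_um <- sqrt(dxv^2 + dyv^2) * pixel_size
  if (is.null(mean_radius)) mean_radius <- section_mean_radius(r_um)
  geo[, "polar_radius"] <- r_um
  geo[, "polar_radius_norm"] <- r_um / mean_radius
  geo[, "polar_angle"] <- atan2(dyv, dxv) %% (2 * pi)
  # incline: angle between major-axis direction and the radius vector
  mx <- cos(geo[, "orientation"])
  my <- sin(geo[, "orientation"])
  rn <- sqrt(dxv^2 + dyv^2)
  dot <- ifelse(rn > 0, (mx * dxv + my * dyv) / rn, NA)
  geo[, "incline"] <- abs(acos(.clip(dot, -1, 1)) - pi / 2)
  out <- data.frame(cell_id = seq_len(n), geo)
  .as_feature_table(out, center, pixel_size, mean_radius, genotype, timepoint)
}

.as_feature_table <- function(df, center, pixel_size, mean_radius,
                              genotype, timepoint) {
  attr(df, "center") <- c(x = unname(center[1]), y = unname(center[2]))
  attr(df, "pixel_size") <- pixel_size
  attr(df, "mean_radius") <- mean_radius
  attr(df, "genotype") <- genotype
  attr(df, "timepoint") <- timepoint
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Write / read a feature table as CSV
#'
#' The CSV carries a versioned comment header with the section metadata so a
#' written table reads back losslessly.
#'
#' @param table a `feature_table`.
#' @param path file path.
#' @return `read_feature_table` returns the `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    "# quanthisto feature table v1",
    sprintf(
      "# center: %.17g %.17g", attr(table, "center")[1],
      attr(table, "center")[2]
    ),
    sprintf("# pixel_size: %.17g", attr(table, "pixel_size")),
    sprintf("# mean_radius: %.17g", attr(table, "mean_radius")),
    sprintf("# genotype: %s", attr(table, "genotype")),
    sprintf("# timepoint: %s", attr(table, "timepoint"))
  )
  writeLines(meta, con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  hdr <- readLines(path, n = 6)
  .assert(grepl("quanthisto feature table", hdr[1]), "not a feature table file")
  val <- function(i) sub("^# [a-z_]+: ", "", hdr[i])
  df <- utils::read.csv(path, comment.char = "#")
  center <- as.numeric(strsplit(val(2), " ")[[1]])
  tp <- suppressWarnings(as.numeric(val(6)))
  gt <- val(5)
  if (identical(gt, "NA")) gt <- NA_character_
  .as_feature_table(
    df, center, as.numeric(val(3)), as.numeric(val(4)),
    gt, tp
  )
}

# ---- internals ----

.cell_pixels <- function(labels, cell_id) {
  .assert(inherits(labels, "label_map"), "labels must be a label_map")
  idx <- which(labels$labels == cell_id)
  .assert(length(idx) > 0, sprintf("cell %s not present", cell_id))
  nr <- nrow(labels$labels)
  list(x = (idx - 1L) %/% nr + 1L, y = (idx - 1L) %% nr + 1L)
}

# moments -> ellipse, coordinates in px
.moments_ellipse <- function(x, y) {
  n <- length(x)
  cx <- mean(x)
  cy <- mean(y)
  if (n == 1L) {
    return(list(
      cx = cx, cy = cy, major = 0, minor = 0, orientation = 0,
      eccentricity = 1, degenerate = TRUE
    ))
  }
  mu20 <- mean((x - cx)^2)
  mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  l2 <- max(l2, 0)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (theta >= pi / 2) theta <- theta - pi
  if (theta < -pi / 2) theta <- theta + pi
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 1
  list(
    cx = cx, cy = cy, major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
    orientation = theta, eccentricity = ecc, degenerate = l2 == 0
  )
}

# area, perimeter (Moore contour tracing, 8-connectivity), boundary radii
.shape_one <- function(x, y) {
  n <- length(x)
  cx <- mean(x)
  cy <- mean(y)
  if (n <= 2L) {
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    return(list(
      area = n, perimeter = if (n == 1L) 4 else 6,
      rmean = mean(r), rsd = if (n > 1) stats::sd(r) else 0,
      rmin = min(r), rmax = max(r)
    ))
  }
  x0 <- min(x)
  y0 <- min(y)
  w <- max(x) - x0 + 3L
  h <- max(y) - y0 + 3L
  m <- matrix(FALSE, h, w) # [row=y, col=x], 1-px pad all around
  m[cbind(y - y0 + 2L, x - x0 + 2L)] <- TRUE
  # boundary pixels: have a 4-neighbour outside the cell
  inner <- m
  inner[2:(h - 1), 2:(w - 1)] <- m[2:(h - 1), 2:(w - 1)] &
    m[1:(h - 2), 2:(w - 1)] & m[3:h, 2:(w - 1)] &
    m[2:(h - 1), 1:(w - 2)] & m[2:(h - 1), 3:w]
  bidx <- which(m & !inner)
  by <- (bidx - 1L) %% h + 1L
  bx <- (bidx - 1L) %/% h + 1L
  r <- sqrt((bx - 2L + x0 - cx)^2 + (by - 2L + y0 - cy)^2)
  per <- .trace_perimeter(m)
  list(
    area = n, perimeter = per,
    rmean = mean(r), rsd = if (length(r) > 1) stats::sd(r) else 0,
    rmin = min(r), rmax = max(r)
  )
}

# Moore-neighbour contour tracing; returns the contour length in px steps
# (1 per axial move, sqrt(2) per diagonal). The mask must have a 1-px
# FALSE pad. Traces the outer contour of the (possibly multi-part) main
# component containing the first foreground pixel in scan order.
.trace_perimeter <- function(m) {
  h <- nrow(m)
  # neighbour offsets clockwise starting East: (dy, dx)
  dy8 <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dx8 <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  start <- which(m)[1L]
  sy <- (start - 1L) %% h + 1L
  sx <- (start - 1L) %/% h + 1L
  # entered the start pixel coming from the West
  cy <- sy
  cx <- sx
  dir <- 0L # index into offsets (0-based) of last move direction
  per <- 0
  first <- TRUE
  repeat {
    # search neighbours clockwise, starting from backtrack direction
    found <- FALSE
    s0 <- (dir + 6L) %% 8L # turn left-ish relative to last move
    for (k in 0:7) {
      d <- (s0 + k) %% 8L
      ny <- cy + dy8[d + 1L]
      nx <- cx + dx8[d + 1L]
      if (m[ny, nx]) {
        per <- per + if (d %% 2L == 0L) 1 else sqrt(2)
        cy <- ny
        cx <- nx
        dir <- d
        found <- TRUE
        break
      }
    }
    if (!found) {
      return(4)
    } # isolated pixel reached via pruning
    if (!first && cy == sy && cx == sx) break
    first <- FALSE
    if (per > 8 * sum(m)) break # safety
  }
  per
}
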