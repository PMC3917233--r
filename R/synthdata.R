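#' Cell-type categories
#'
#' The five vascular cell-type categories used throughout the package:
#' xylem vessels together with xylem parenchyma, xylem fibers, cambial cells,
#' phloem bundle cells (sieve elements plus companion cells), and phloem
#' parenchyma.
#'
#' @return character vector of the five class names, in canonical order.
#' @export
cell_classes <- function() {
  c(
    "xylem_vessel_parenchyma", "xylem_fiber", "cambium",
    "phloem_bundle", "phloem_parenchyma"
  )
}

#' Specification of a synthetic cross-section
#'
#' Describes the concentric geometry of a radially organized organ section:
#' a central xylem disc of mainly large, radially oriented cells, a thin
#' cambium ring of small orthoradial cells, and an outer phloem annulus of
#' orthoradial cells with clusters of small phloem-bundle cells at equally
#' spaced "poles" along the circumference. All physical quantities are in
#' micrometres and converted once through `pixel_size`.
#'
#' Defaults portray a mid-stage Arabidopsis hypocotyl: a 480 µm section
#' radius, poles every ~140 µm of cambial arc, 0.35 µm/px sampling, and cell
#' sizes chosen per tissue so a default section holds on the order of a
#' thousand cells.
#'
#' @param zone_radii named numeric, µm: `xylem_outer` < `cambium_outer` <
#'   `phloem_outer`.
#' @param pixel_size µm per pixel.
#' @param cell_size_params named list per cell type with `area` (mean µm²),
#'   `elongation` (major/minor axis ratio) and `orientation`
#'   (`"radial"`, `"orthoradial"` or `"mixed"`).
#' @param n_pole number of phloem poles; overrides `pole_arc_spacing` when
#'   not `NULL` (0 means no poles).
#' @param pole_arc_spacing arc distance between adjacent poles along the
#'   cambial circumference, µm.
#' @param vessel_fraction fraction of the xylem radius occupied by the inner
#'   vessel/parenchyma zone (the remainder holds fibers).
#' @param bundle_depth radial depth of the phloem-bundle ring, µm.
#' @param bundle_arc arc width of one pole's bundle cluster, µm.
#' @param wall_width cell-wall width in pixels (odd).
#' @param noise Gaussian intensity noise sd (8-bit scale).
#' @param wall_intensity,lumen_intensity,background_intensity 8-bit levels.
#' @param margin padding beyond the section radius, µm.
#' @param jitter relative jitter of band edges and arc widths in (0, 0.4).
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return an object of class `section_spec`.
#' @seealso [generate_section()]
#' @export
section_spec <- function(zone_radii = c(
                           xylem_outer = 250, cambium_outer = 280,
                           phloem_outer = 480
                         ),
                         pixel_size = 0.35,
                         cell_size_params = list(
                           xylem_vessel_parenchyma = list(area = 900, elongation = 2.5, orientation = "radial"),
                           xylem_fiber = list(area = 450, elongation = 2.5, orientation = "radial"),
                           cambium = list(area = 200, elongation = 4, orientation = "orthoradial"),
                           phloem_bundle = list(area = 250, elongation = 1.5, orientation = "orthoradial"),
                           phloem_parenchyma = list(area = 1300, elongation = 2, orientation = "orthoradial")
                         ),
                         n_pole = NULL,
                         pole_arc_spacing = 140,
                         vessel_fraction = 0.65,
                         bundle_depth = 40,
                         bundle_arc = 70,
                         wall_width = 3,
                         noise = 8,
                         wall_intensity = 60,
                         lumen_intensity = 200,
                         background_intensity = 230,
                         margin = 30,
                         jitter = 0.12,
                         seed = 1L) {
  zr <- unlist(zone_radii)
  .assert(
    all(c("xylem_outer", "cambium_outer", "phloem_outer") %in% names(zr)),
    "zone_radii must name xylem_outer, cambium_outer, phloem_outer"
  )
  .assert(
    zr[["xylem_outer"]] > 0 && zr[["xylem_outer"]] < zr[["cambium_outer"]] &&
      zr[["cambium_outer"]] < zr[["phloem_outer"]],
    "zone radii must satisfy 0 < xylem_outer < cambium_outer < phloem_outer"
  )
  .assert(pixel_size > 0, "pixel_size must be positive")
  if (!is.null(n_pole)) .assert(n_pole >= 0, "n_pole must be >= 0")
  if (is.null(n_pole)) {
    .assert(
      !is.null(pole_arc_spacing) && pole_arc_spacing > 0,
      "pole_arc_spacing must be positive when n_pole is not given"
    )
  }
  .assert(wall_width >= 1 && wall_width %% 2 == 1, "wall_width must be odd and >= 1")
  .assert(
    all(cell_classes() %in% names(cell_size_params)),
    "cell_size_params must cover all five cell classes"
  )
  structure(
    list(
      zone_radii = zr, pixel_size = pixel_size,
      cell_size_params = cell_size_params,
      n_pole = n_pole, pole_arc_spacing = pole_arc_spacing,
      vessel_fraction = vessel_fraction,
      bundle_depth = bundle_depth, bundle_arc = bundle_arc,
      wall_width = as.integer(wall_width), noise = noise,
      wall_intensity = wall_intensity, lumen_intensity = lumen_intensity,
      background_intensity = background_intensity,
      margin = margin, jitter = jitter, seed = as.integer(seed)
    ),
    class = "section_spec"
  )
}

#' @export
print.section_spec <- function(x, ...) {
  cat(
    "section_spec: radii", paste(round(x$zone_radii), collapse = "/"),
    "um,", x$pixel_size, "um/px, seed", x$seed, "\n"
  )
  invisible(x)
}

# number of poles implied by a spec at the cambium radius
.spec_n_pole <- function(spec) {
  if (!is.null(spec$n_pole)) {
    return(as.integer(spec$n_pole))
  }
  r <- spec$zone_radii[["cambium_outer"]]
  max(0L, as.integer(floor(2 * pi * r / spec$pole_arc_spacing)))
}

# Build the band/arc tessellation of one annular zone.
# Returns a list of bands; each band: r1, r2 (px), arc_edges (rad, from
# offset, increasing, covering 2*pi), classes (per arc).
.zone_bands <- function(r1, r2, area_um2, elong, orientation, px, jit,
                        arc_builder = NULL, class_default = NULL) {
  a_px <- area_um2 / px^2
  if (orientation == "radial") {
    h <- sqrt(a_px * elong)
    w <- a_px / h
  } else if (orientation == "orthoradial") {
    w <- sqrt(a_px * elong)
    h <- a_px / w
  } else { # mixed
    h <- sqrt(a_px)
    w <- h
  }
  nb <- max(1L, as.integer(round((r2 - r1) / h)))
  edges <- seq(r1, r2, length.out = nb + 1)
  if (nb > 1) {
    bw <- diff(edges)[1]
    edges[2:nb] <- edges[2:nb] + stats::runif(nb - 1, -jit * bw, jit * bw)
  }
  bands <- vector("list", nb)
  for (b in seq_len(nb)) {
    rm <- (edges[b] + edges[b + 1]) / 2
    if (!is.null(arc_builder)) {
      ab <- arc_builder(rm, w)
      arc <- ab$edges
      cls <- ab$classes
      off <- ab$offset
    } else {
      na <- max(1L, as.integer(round(2 * pi * rm / w)))
      if (2 * pi * rm < 2 * w) na <- 1L
      widths <- stats::runif(na, 1 - jit, 1 + jit)
      arc <- c(0, cumsum(widths) / sum(widths) * 2 * pi)
      cls <- rep(class_default, na)
      off <- stats::runif(1, 0, 2 * pi)
    }
    bands[[b]] <- list(
      r1 = edges[b], r2 = edges[b + 1], offset = off,
      arc_edges = arc, classes = cls
    )
  }
  bands
}

#' Generate a synthetic cross-section image with ground truth
#'
#' Rasterizes the tessellation described by a [section_spec()]: cells are
#' annular-sector "bricks" laid out in concentric bands per tissue zone, with
#' dark walls between them on a light lumen (toluidine-blue bright-field
#' appearance), Gaussian intensity noise, and filled binary masks of the
#' section disc and xylem disc. Ground truth carries the wall-free label map,
#' the class of every cell and its analytic geometry (centroid, unit
#' major-axis vector, area).
#'
#' @param spec a [section_spec()].
#' @return list with elements `image` (a `section_image`), `truth` (a
#'   `ground_truth`: `label_map`, `cell_classes`, `cell_geometry`), and
#'   `masks` (a `mask_pair`).
#' @examples
#' sec <- generate_section(section_spec(
#'   zone_radii = c(xylem_outer = 60, cambium_outer = 72, phloem_outer = 110),
#'   pixel_size = 1, seed = 7
#' ))
#' sec$truth$label_map$n_cells
#' @export
generate_section <- function(spec) {
  .assert(inherits(spec, "section_spec"), "spec must be a section_spec")
  local_seed(spec$seed, .generate_section_impl(spec))
}

.generate_section_impl <- function(spec) {
  px <- spec$pixel_size
  rx <- spec$zone_radii[["xylem_outer"]] / px
  rc <- spec$zone_radii[["cambium_outer"]] / px
  rp <- spec$zone_radii[["phloem_outer"]] / px
  half <- ceiling(rp + spec$margin / px)
  side <- 2L * half + 1L
  cx <- half + 1
  cy <- half + 1
  csp <- spec$cell_size_params
  jit <- spec$jitter

  n_pole <- .spec_n_pole(spec)
  pole_angles <- if (n_pole > 0) {
    (seq_len(n_pole) - 1) / n_pole * 2 * pi + stats::runif(1, 0, 2 * pi)
  } else {
    numeric(0)
  }

  # arc builder for the bundle ring: small bundle arcs clustered at the pole
  # angles, parenchyma arcs between
  bundle_halfw_px <- spec$bundle_arc / 2 / px
  w_bundle_px <- local({
    p <- csp$phloem_bundle
    sqrt(p$area / px^2 * p$elongation)
  })
  bundle_builder <- function(rm, w_par) {
    if (n_pole == 0) {
      na <- max(1L, as.integer(round(2 * pi * rm / w_par)))
      widths <- stats::runif(na, 1 - jit, 1 + jit)
      return(list(
        edges = c(0, cumsum(widths) / sum(widths) * 2 * pi),
        classes = rep("phloem_parenchyma", na), offset = stats::runif(1, 0, 2 * pi)
      ))
    }
    halfw <- bundle_halfw_px / rm # rad
    kb <- max(1L, as.integer(round(2 * bundle_halfw_px / w_bundle_px)))
    gap <- 2 * pi / n_pole - 2 * halfw
    kp <- max(1L, as.integer(round(gap * rm / w_par)))
    edges <- 0
    classes <- character(0)
    for (p in seq_len(n_pole)) {
      base <- (p - 1) * 2 * pi / n_pole
      be <- seq(base, base + 2 * halfw, length.out = kb + 1)[-1]
      edges <- c(edges, be)
      classes <- c(classes, rep("phloem_bundle", kb))
      ge <- seq(base + 2 * halfw, base + 2 * pi / n_pole, length.out = kp + 1)[-1]
      edges <- c(edges, ge)
      classes <- c(classes, rep("phloem_parenchyma", kp))
    }
    # offset so that pole p sits centred at pole_angles[p]
    list(edges = edges, classes = classes, offset = pole_angles[1] - bundle_halfw_px / rm)
  }

  zones <- list()
  vf <- spec$vessel_fraction
  z <- csp$xylem_vessel_parenchyma
  zones <- c(zones, list(.zone_bands(0, vf * rx, z$area, z$elongation, z$orientation,
    px, jit,
    class_default = "xylem_vessel_parenchyma"
  )))
  z <- csp$xylem_fiber
  zones <- c(zones, list(.zone_bands(vf * rx, rx, z$area, z$elongation, z$orientation,
    px, jit,
    class_default = "xylem_fiber"
  )))
  z <- csp$cambium
  zones <- c(zones, list(.zone_bands(rx, rc, z$area, z$elongation, z$orientation,
    px, jit,
    class_default = "cambium"
  )))
  bd <- spec$bundle_depth / px
  z <- csp$phloem_parenchyma
  w_par_px <- sqrt(z$area / px^2 * z$elongation)
  zones <- c(zones, list(.zone_bands(rc, rc + bd, csp$phloem_bundle$area,
    csp$phloem_bundle$elongation, "orthoradial", px, jit,
    arc_builder = function(rm, w) bundle_builder(rm, w_par_px)
  )))
  zones <- c(zones, list(.zone_bands(rc + bd, rp, z$area, z$elongation, z$orientation,
    px, jit,
    class_default = "phloem_parenchyma"
  )))

  # rasterize
  xs <- matrix(rep(seq_len(side), each = side), nrow = side) # col index (x)
  ys <- matrix(rep(seq_len(side), times = side), nrow = side) # row index (y)
  dx <- xs - cx
  dy <- ys - cy
  rr <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)

  lab <- matrix(0L, side, side)
  records <- list()
  next_id <- 0L
  all_edges <- unlist(lapply(zones, function(bs) vapply(bs, `[[`, 1, "r1")))
  for (bands in zones) {
    for (band in bands) {
      sel <- which(rr >= band$r1 & rr < band$r2)
      if (!length(sel)) next
      a <- (ang[sel] - band$offset) %% (2 * pi)
      na <- length(band$arc_edges) - 1L
      ai <- findInterval(a, band$arc_edges, rightmost.closed = TRUE)
      ai[ai < 1L] <- 1L
      ai[ai > na] <- na
      lab[sel] <- next_id + ai
      # analytic per-arc geometry
      r1 <- band$r1
      r2 <- band$r2
      th1 <- band$arc_edges[-(na + 1L)] + band$offset
      th2 <- band$arc_edges[-1L] + band$offset
      dth <- th2 - th1
      bis <- (th1 + th2) / 2
      rcent <- if (r2 > r1) {
        (2 / 3) * (r2^3 - r1^3) / (r2^2 - r1^2) * ifelse(dth > 0, sin(dth / 2) / (dth / 2), 1)
      } else {
        rep((r1 + r2) / 2, na)
      }
      radial <- (r2 - r1) > rcent * dth # elongation direction of this band
      mx <- ifelse(radial, cos(bis), -sin(bis))
      my <- ifelse(radial, sin(bis), cos(bis))
      records[[length(records) + 1L]] <- data.frame(
        cell_id = next_id + seq_len(na),
        class = band$classes,
        cx = cx + rcent * cos(bis),
        cy = cy + rcent * sin(bis),
        major_x = mx, major_y = my,
        area_um2 = 0.5 * dth * (r2^2 - r1^2) * px^2,
        stringsAsFactors = FALSE
      )
      next_id <- next_id + na
    }
  }
  geom <- do.call(rbind, records)

  # walls: pixels bordering a different label (4-neighbour), thickened
  b <- matrix(FALSE, side, side)
  b[, -side] <- b[, -side] | (lab[, -side] != lab[, -1])
  b[, -1] <- b[, -1] | (lab[, -1] != lab[, -side])
  b[-side, ] <- b[-side, ] | (lab[-side, ] != lab[-1, ])
  b[-1, ] <- b[-1, ] | (lab[-1, ] != lab[-side, ])
  if (spec$wall_width > 1) {
    b <- EBImage::dilate(b, EBImage::makeBrush(spec$wall_width, "disc")) > 0
  }
  inside <- rr <= rp
  # the section's rim wall keeps its full width (it extends slightly past
  # the nominal radius), like every interior wall
  wall <- b
  lab[wall | !inside] <- 0L

  # drop cells erased by walls, compact ids
  counts <- tabulate(lab, nbins = next_id)
  keep <- which(counts >= 9L)
  remap <- integer(next_id)
  remap[keep] <- seq_along(keep)
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  geom <- geom[geom$cell_id %in% keep, , drop = FALSE]
  geom$cell_id <- remap[geom$cell_id]
  geom <- geom[order(geom$cell_id), , drop = FALSE]
  rownames(geom) <- NULL

  # image
  img <- matrix(spec$background_intensity, side, side)
  img[inside] <- spec$lumen_intensity
  img[wall] <- spec$wall_intensity # includes the rim wall ring
  if (spec$noise > 0) {
    img <- img + matrix(stats::rnorm(side * side, 0, spec$noise), side, side)
  }
  img <- .clip(round(img), 0, 255)

  classes <- geom$class
  names(classes) <- geom$cell_id
  list(
    image = section_image(img, pixel_size = px, center = c(x = cx, y = cy)),
    truth = structure(
      list(
        label_map = label_map(lab),
        cell_classes = classes,
        cell_geometry = geom,
        pole_angles = pole_angles,
        pixel_size = px,
        center = c(x = cx, y = cy)
      ),
      class = "ground_truth"
    ),
    masks = mask_pair(
      section = inside, xylem = rr <= rx,
      provenance = "synthetic"
    )
  )
}

#' Generate a synthetic reporter-stained pole ring image
#'
#' Emulates a section in which phloem bundles are marked by a dark
#' histochemical stain: dark Gaussian foci on a bright background, centered
#' on a ring at the cambium radius and equally arc-spaced, plus additive
#' Gaussian noise. Used to exercise [ring_profile()] and [bayesian_period()].
#'
#' @param spec a [section_spec()]; pole count/spacing and geometry are taken
#'   from it.
#' @param focus_intensity depth of each dark focus (8-bit units).
#' @param background_sd additive Gaussian noise sd.
#' @param focus_sigma Gaussian radius of a focus, px.
#' @return a `section_image`.
#' @export
generate_gus_ring <- function(spec, focus_intensity = 120, background_sd = 5,
                              focus_sigma = 6) {
  .assert(inherits(spec, "section_spec"), "spec must be a section_spec")
  px <- spec$pixel_size
  rc <- spec$zone_radii[["cambium_outer"]] / px
  .assert(rc > 0, "ring radius must be positive")
  n_pole <- .spec_n_pole(spec)
  .assert(n_pole > 0, "spec must define at least one pole (n_pole or pole_arc_spacing)")
  local_seed(spec$seed, {
    half <- ceiling(rc * 1.3 + 20)
    side <- 2L * half + 1L
    cx <- half + 1
    cy <- half + 1
    img <- matrix(spec$background_intensity, side, side)
    th <- (seq_len(n_pole) - 1) / n_pole * 2 * pi
    xs <- rep(seq_len(side), each = side)
    ys <- rep(seq_len(side), times = side)
    for (t in th) {
      fx <- cx + rc * cos(t)
      fy <- cy + rc * sin(t)
      d2 <- (xs - fx)^2 + (ys - fy)^2
      img <- img - focus_intensity * matrix(exp(-d2 / (2 * focus_sigma^2)), side, side)
    }
    if (background_sd > 0) {
      img <- img + matrix(stats::rnorm(side * side, 0, background_sd), side, side)
    }
    section_image(.clip(img, 0, 255), pixel_size = px, center = c(x = cx, y = cy))
  })
}

#' Split a section image into a grid of tiles
#'
#' Cuts the image into `grid[1] x grid[2]` tiles of `tile_px` pixels each,
#' padding with the background (zero) where the grid extends past the image.
#' The returned manifest makes [stitch_tiles()] an exact inverse on the
#' original extent.
#'
#' @param image a `section_image` or numeric matrix.
#' @param grid integer `c(rows, cols)`.
#' @param tile_px tile side length in pixels.
#' @return list with `tiles` (row-major list of matrices) and `manifest`
#'   (grid shape, tile size, original dimensions, row-major order).
#' @export
tile_image <- function(image, grid, tile_px) {
  m <- if (inherits(image, "section_image")) image$pixels else image
  .assert(tile_px > 0, "tile_px must be positive")
  .assert(length(grid) == 2 && all(grid >= 1), "grid must be c(rows, cols) >= 1")
  nr <- nrow(m)
  nc <- ncol(m)
  .assert(
    grid[1] * tile_px >= nr && grid[2] * tile_px >= nc,
    "grid does not cover the image"
  )
  big <- matrix(0, grid[1] * tile_px, grid[2] * tile_px)
  big[seq_len(nr), seq_len(nc)] <- m
  tiles <- vector("list", grid[1] * grid[2])
  k <- 0L
  for (i in seq_len(grid[1])) {
    for (j in seq_len(grid[2])) {
      k <- k + 1L
      tiles[[k]] <- big[
        ((i - 1) * tile_px + 1):(i * tile_px),
        ((j - 1) * tile_px + 1):(j * tile_px)
      ]
    }
  }
  manifest <- list(
    rows = grid[1], cols = grid[2], tile_px = tile_px,
    image_dim = c(nr, nc), order = "row-major",
    pixel_size = if (inherits(image, "section_image")) image$pixel_size else NA_real_,
    center = if (inherits(image, "section_image")) unname(image$center) else NULL
  )
  list(tiles = tiles, manifest = manifest)
}

#' Write / read a tile manifest as JSON
#' @param manifest manifest list from [tile_image()].
#' @param path file path.
#' @return `read_manifest` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
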