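#' Section image container
#'
#' A 2-D intensity grid with a physical pixel size and an optional section
#' center. Pixels are stored as a plain numeric matrix indexed
#' `pixels[row = y, col = x]` (1-based, origin top-left); centers and
#' centroids are stored as `(x, y)` pairs in pixel units.
#'
#' @param pixels numeric matrix of intensities (8- or 16-bit scale).
#' @param pixel_size µm per pixel (> 0).
#' @param center optional `c(x, y)` center in pixels.
#' @param depth bit depth, 8 or 16; sets the intensity scale maximum.
#' @return object of class `section_image`.
#' @export
section_image <- function(pixels, pixel_size, center = NULL, depth = 8L) {
  .assert(is.matrix(pixels) && length(pixels) > 0, "pixels must be a non-empty matrix")
  .assert(is.numeric(pixel_size) && pixel_size > 0, "pixel_size must be > 0")
  if (!is.null(center)) {
    .assert(length(center) == 2, "center must be c(x, y)")
    center <- c(x = unname(center[1]), y = unname(center[2]))
  }
  .assert(depth %in% c(8L, 16L), "depth must be 8 or 16")
  structure(
    list(
      pixels = pixels, pixel_size = pixel_size, center = center,
      depth = as.integer(depth)
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(
    "section_image:", nrow(x$pixels), "x", ncol(x$pixels), "px,",
    x$pixel_size, "um/px,",
    if (is.null(x$center)) "center unset" else paste0("center (", paste(round(x$center, 1), collapse = ", "), ")"),
    "\n"
  )
  invisible(x)
}

# intensity scale maximum for an image
.vmax <- function(image) if (image$depth == 16L) 65535 else 255

#' Label map container
#'
#' An integer-labeled segmentation: 0 marks background and cell walls,
#' labels 1..n_cells mark cells. Construction compacts labels to the
#' contiguous range 1..n_cells.
#'
#' @param labels non-negative integer matrix.
#' @return object of class `label_map` with fields `labels`, `n_cells`.
#' @export
label_map <- function(labels) {
  .assert(is.matrix(labels), "labels must be a matrix")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  .assert(all(labels >= 0L), "labels must be non-negative")
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    nz <- labels > 0L
    labels[nz] <- remap[labels[nz]]
  }
  structure(list(labels = labels, n_cells = length(ids)), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(
    "label_map:", nrow(x$labels), "x", ncol(x$labels), "px,",
    x$n_cells, "cells\n"
  )
  invisible(x)
}

#' Mask pair for quality control
#'
#' Binary masks of the whole transverse section area and of the xylem area,
#' in the same pixel frame as the label map they control.
#'
#' @param section logical (or 0/1) matrix: whole-section area.
#' @param xylem logical matrix: xylem area; must be contained in `section`.
#' @param provenance `"manual"` or `"synthetic"`.
#' @return object of class `mask_pair`.
#' @export
mask_pair <- function(section, xylem, provenance = c("manual", "synthetic")) {
  provenance <- match.arg(provenance)
  section <- section > 0
  xylem <- xylem > 0
  .assert(
    identical(dim(section), dim(xylem)),
    "section and xylem masks must share one pixel frame"
  )
  .assert(!any(xylem & !section), "xylem mask must lie inside the section mask")
  structure(
    list(section = section, xylem = xylem, provenance = provenance),
    class = "mask_pair"
  )
}

#' Stitch image tiles back into a single section image
#'
#' Places tiles in row-major order with no blending (tiles abut exactly) and
#' crops to the original extent recorded in the manifest, so that
#' `stitch_tiles(tile_image(img, ...))` reproduces `img` bit-exactly.
#'
#' @param tiles row-major list of equally sized tile matrices.
#' @param manifest manifest list as produced by [tile_image()] (fields
#'   `rows`, `cols`, `tile_px`, `image_dim`, optionally `pixel_size`,
#'   `center`).
#' @return a `section_image`.
#' @export
stitch_tiles <- function(tiles, manifest) {
  rows <- manifest$rows
  cols <- manifest$cols
  tp <- manifest$tile_px
  .assert(length(tiles) == rows * cols, sprintf(
    "manifest declares %d x %d = %d tiles but %d were given",
    rows, cols, rows * cols, length(tiles)
  ))
  k <- 0L
  big <- matrix(0, rows * tp, cols * tp)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      k <- k + 1L
      t <- tiles[[k]]
      if (is.null(t)) {
        stop(sprintf("missing tile at grid position (%d, %d)", i, j), call. = FALSE)
      }
      if (!identical(dim(t), c(as.integer(tp), as.integer(tp))) &&
        !identical(dim(t), c(tp, tp))) {
        stop(sprintf(
          "tile at grid position (%d, %d) has shape %s, expected %d x %d",
          i, j, paste(dim(t), collapse = " x "), tp, tp
        ), call. = FALSE)
      }
      big[((i - 1) * tp + 1):(i * tp), ((j - 1) * tp + 1):(j * tp)] <- t
    }
  }
  dm <- manifest$image_dim
  if (!is.null(dm)) big <- big[seq_len(dm[1]), seq_len(dm[2]), drop = FALSE]
  ps <- manifest$pixel_size
  if (is.null(ps) || is.na(ps)) ps <- 1
  section_image(big,
    pixel_size = ps,
    center = if (!is.null(manifest$center)) unlist(manifest$center) else NULL
  )
}

#' Preprocess an image: gamma, contrast, brightness
#'
#' Applies, in this fixed order, gamma correction, contrast scaling and
#' brightness shift on the normalized intensity scale:
#' `v' = clip(contrast * (v/vmax)^gamma + brightness, 0, 1) * vmax`.
#'
#' @param image a `section_image`.
#' @param gamma gamma exponent (> 0); 1 leaves values unchanged.
#' @param contrast multiplicative gain.
#' @param brightness additive offset on the normalized scale.
#' @return a `section_image`.
#' @export
preprocess <- function(image, gamma = 1, contrast = 1, brightness = 0) {
  .assert(inherits(image, "section_image"), "image must be a section_image")
  .assert(is.numeric(gamma) && gamma > 0, "gamma must be > 0")
  vmax <- .vmax(image)
  v <- .clip(contrast * (image$pixels / vmax)^gamma + brightness, 0, 1) * vmax
  out <- image
  out$pixels <- v
  out
}

#' Adaptive (local Gaussian mean) binarization of cell walls
#'
#' A pixel is foreground (wall) iff its intensity is below the
#' Gaussian-weighted local mean minus `offset`. Walls are dark in
#' toluidine-blue bright-field images, so the foreground is the cell-wall
#' line network and cells are its complement.
#'
#' @param image a `section_image`.
#' @param window_px odd window size (>= 3) of the Gaussian kernel.
#' @param offset subtracted from the local mean before comparison, in
#'   intensity units; larger values are more conservative.
#' @return logical matrix, `TRUE` = wall.
#' @export
binarize_adaptive <- function(image, window_px = 31L, offset = 10) {
  .assert(inherits(image, "section_image"), "image must be a section_image")
  .assert(
    window_px >= 3 && window_px %% 2 == 1,
    "window_px must be odd and >= 3"
  )
  .assert(
    window_px <= min(dim(image$pixels)),
    "window_px larger than the image"
  )
  brush <- EBImage::makeBrush(window_px, shape = "gaussian", sigma = window_px / 6)
  brush <- brush / sum(brush)
  localmean <- EBImage::filter2(image$pixels, brush)
  image$pixels < (localmean - offset)
}

#' Morphological clean-up of a binary mask
#'
#' Applies `n_erosions` erosions followed by `n_dilations` dilations with a
#' disc structuring element, discarding isolated noise pixels and
#' regularizing boundaries.
#'
#' @param mask logical (or 0/1) matrix.
#' @param n_erosions,n_dilations operation counts.
#' @param selem_size odd diameter of the disc structuring element, px.
#' @return logical matrix.
#' @export
morph_clean <- function(mask, n_erosions = 2L, n_dilations = 1L, selem_size = 3L) {
  .assert(is.matrix(mask), "mask must be a matrix")
  m <- mask > 0
  if (!any(m)) {
    return(m)
  }
  .assert(selem_size >= 1 && selem_size %% 2 == 1, "selem_size must be odd")
  kern <- EBImage::makeBrush(selem_size, "disc")
  for (i in seq_len(n_erosions)) m <- EBImage::erode(m, kern) > 0
  for (i in seq_len(n_dilations)) m <- EBImage::dilate(m, kern) > 0
  m
}

#' Watershed segmentation of cells from a wall mask
#'
#' Seeds are the local maxima of the distance transform of the non-wall
#' region (automatic seeding, no manual input); the watershed is computed on
#' the inverted distance transform, so each basin becomes one cell. Labels
#' are compacted to 1..n after removing slivers below `min_cell_px`.
#'
#' @param image a `section_image` (geometry/pixel size carrier; the
#'   segmentation itself runs on the mask).
#' @param wall_mask logical matrix from [binarize_adaptive()] /
#'   [morph_clean()], aligned with `image`.
#' @param tolerance minimum height difference between a basin and its
#'   boundary for it to stay a separate object (watershed merge tolerance).
#' @param min_cell_px minimum object area in pixels.
#' @return a `label_map`.
#' @export
watershed_segment <- function(image, wall_mask, tolerance = 2, min_cell_px = 20L) {
  .assert(inherits(image, "section_image"), "image must be a section_image")
  .assert(
    identical(dim(image$pixels), dim(wall_mask)),
    "wall mask must be aligned with the image"
  )
  cells <- !(wall_mask > 0)
  if (!any(cells)) {
    warning("wall mask covers the whole frame: zero cells")
    return(label_map(matrix(0L, nrow(wall_mask), ncol(wall_mask))))
  }
  dm <- EBImage::distmap(cells)
  ws <- EBImage::watershed(dm, tolerance = tolerance)
  lab <- matrix(as.integer(ws), nrow(ws), ncol(ws))
  if (min_cell_px > 0 && any(lab > 0L)) {
    sizes <- tabulate(lab, nbins = max(lab))
    drop <- which(sizes < min_cell_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  label_map(lab)
}

#' Mis-segmentation rate against ground truth
#'
#' A ground-truth cell counts as mis-segmented if no predicted label overlaps
#' it with an intersection-over-union of at least `iou_min`; this covers
#' merges (the engulfing label has too large a union), splits (each fragment
#' too small an intersection) and misses.
#'
#' @param labels predicted `label_map`.
#' @param truth a `ground_truth` (from [generate_section()]) or a
#'   `label_map` of true cells.
#' @param iou_min match threshold.
#' @return mis-segmented fraction in `[0, 1]`, with attributes
#'   `missegmented` (truth ids) and `n_truth`.
#' @export
segmentation_error_rate <- function(labels, truth, iou_min = 0.5) {
  .assert(inherits(labels, "label_map"), "labels must be a label_map")
  tl <- if (inherits(truth, "ground_truth")) truth$label_map else truth
  .assert(inherits(tl, "label_map"), "truth must carry a label_map")
  .assert(tl$n_cells > 0, "ground truth is empty")
  .assert(
    identical(dim(labels$labels), dim(tl$labels)),
    "label maps must share one pixel frame"
  )
  tv <- as.vector(tl$labels)
  pv <- as.vector(labels$labels)
  nt <- tl$n_cells
  np <- labels$n_cells
  t_sizes <- tabulate(tv, nbins = nt)
  p_sizes <- tabulate(pv, nbins = max(np, 1L))
  sel <- tv > 0L & pv > 0L
  key <- (as.numeric(tv[sel]) - 1) * np + as.numeric(pv[sel])
  ov <- tabulate(key, nbins = nt * np)
  nz <- which(ov > 0)
  ti <- (nz - 1) %/% np + 1
  pi_ <- (nz - 1) %% np + 1
  inter <- ov[nz]
  iou <- inter / (t_sizes[ti] + p_sizes[pi_] - inter)
  best <- rep(0, nt)
  agg <- tapply(iou, ti, max)
  best[as.integer(names(agg))] <- agg
  miss <- which(best < iou_min)
  structure(length(miss) / nt, missegmented = miss, n_truth = nt)
}
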