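#' Filter objects outside the section mask
#'
#' Drops rows whose centroid lies outside the whole-section mask — typically
#' mis-segmented objects such as dirt contaminations or shed epidermal /
#' cortex cells beyond the section's average radius.
#'
#' Mask membership is tested at the rounded centroid pixel (not by pixel
#' majority), which is fast and adequate for compact cells.
#'
#' @param table `feature_table` / `data.frame` with `centroid_x`,
#'   `centroid_y` (px).
#' @param masks a `mask_pair`.
#' @return list with `kept` (filtered table) and `dropped_ids`.
#' @export
filter_outside <- function(table, masks) {
  .assert(inherits(masks, "mask_pair"), "masks must be a mask_pair")
  .assert(any(masks$section), "section mask is empty")
  inside <- .centroid_in_mask(table, masks$section)
  list(
    kept = table[inside, , drop = FALSE],
    dropped_ids = table$cell_id[!inside]
  )
}

#' Correct mis-assigned xylem identities with the xylem-area mask
#'
#' SVM classifiers frequently confuse xylem vessels with phloem parenchyma
#' cells, whose outlines converge during secondary growth. This corrects
#' class assignments against the mask-defined xylem area: cells classed as a
#' xylem type whose centroid lies outside the xylem mask are reassigned to
#' phloem parenchyma, and (with `direction = "both"`, the default policy)
#' phloem-parenchyma cells inside the xylem mask are reassigned to the xylem
#' vessel/parenchyma class. After correction no xylem-class centroid lies
#' outside the xylem mask. The operation is idempotent and preserves the
#' row count.
#'
#' @param table classified table (`class` column plus centroids).
#' @param masks a `mask_pair`.
#' @param direction `"both"` (bidirectional, default), `"to_phloem"` (only
#'   relabel xylem classes found outside) or `"to_xylem"`.
#' @return list with `table` (corrected) and `changes` (data.frame
#'   `cell_id`, `old`, `new`).
#' @export
correct_xylem <- function(table, masks, direction = c("both", "to_phloem", "to_xylem")) {
  direction <- match.arg(direction)
  .assert("class" %in% names(table), "table must have a class column")
  .assert(inherits(masks, "mask_pair"), "masks must be a mask_pair")
  cls <- as.character(table$class)
  in_xylem <- .centroid_in_mask(table, masks$xylem)
  xylem_classes <- c("xylem_vessel_parenchyma", "xylem_fiber")
  new <- cls
  if (direction %in% c("both", "to_phloem")) {
    out_x <- cls %in% xylem_classes & !in_xylem
    new[out_x] <- "phloem_parenchyma"
  }
  if (direction %in% c("both", "to_xylem")) {
    in_p <- cls == "phloem_parenchyma" & in_xylem
    new[in_p] <- "xylem_vessel_parenchyma"
  }
  changed <- which(new != cls)
  table$class <- new
  list(
    table = table,
    changes = data.frame(
      cell_id = table$cell_id[changed],
      old = cls[changed], new = new[changed]
    )
  )
}

.centroid_in_mask <- function(table, mask) {
  .assert(
    all(c("centroid_x", "centroid_y") %in% names(table)),
    "table must have centroid_x / centroid_y columns"
  )
  xi <- as.integer(round(table$centroid_x))
  yi <- as.integer(round(table$centroid_y))
  ok <- xi >= 1 & xi <= ncol(mask) & yi >= 1 & yi <= nrow(mask)
  inside <- logical(nrow(table))
  inside[ok] <- mask[cbind(yi[ok], xi[ok])]
  inside
}

#' Read / write binary masks as PNG
#'
#' @param path PNG file path.
#' @param mask logical matrix.
#' @return `read_mask` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
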