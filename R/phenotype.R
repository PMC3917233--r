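#' Phenoprint of one genotype x time point
#'
#' Summarizes a set of classified, quality-controlled sections as a vector
#' of 8 section-level statistics: median total cell count, median total
#' transverse area (µm², sum of cell areas), the five cell-type proportions
#' (medians of the per-section proportions, renormalized to sum to 1) and
#' the median incline angle.
#'
#' @param tables list of classified tables (columns `class`, `area`,
#'   `incline`), one per section.
#' @param genotype,timepoint metadata (timepoint in days after
#'   germination).
#' @return named numeric of length 8, class `phenoprint`, with attributes
#'   `genotype`, `timepoint`, `n_sections`, `composition`.
#' @export
compute_phenoprint <- function(tables, genotype = NA_character_, timepoint = NA_real_) {
  .assert(is.list(tables) && length(tables) >= 1, "need at least one section table")
  lapply(tables, function(t) {
    .assert(
      all(c("class", "area", "incline") %in% names(t)),
      "each table needs class, area and incline columns"
    )
  })
  classes <- cell_classes()
  per_section <- vapply(tables, function(t) {
    prop <- vapply(classes, function(cl) mean(t$class == cl), numeric(1))
    c(
      n_cells = nrow(t), total_area_um2 = sum(t$area), prop,
      median_incline = stats::median(t$incline)
    )
  }, numeric(8))
  v <- apply(per_section, 1, stats::median)
  pr <- v[classes]
  .assert(sum(pr) > 0, "no cells in any of the five classes")
  v[classes] <- pr / sum(pr)
  names(v) <- c("n_cells", "total_area_um2", paste0("prop_", classes), "median_incline")
  structure(v,
    class = "phenoprint", genotype = genotype, timepoint = timepoint,
    n_sections = length(tables),
    composition = "median(count), median(area), 5 class proportions, median(incline)"
  )
}

#' Assemble phenoprints into a samples-by-variables matrix
#'
#' @param phenoprints list of [compute_phenoprint()] results.
#' @return numeric matrix, one row per phenoprint, rownames
#'   `genotype_timepoint`.
#' @export
phenoprint_matrix <- function(phenoprints) {
  .assert(length(phenoprints) >= 1, "no phenoprints given")
  m <- do.call(rbind, lapply(phenoprints, unclass))
  rownames(m) <- vapply(phenoprints, function(p) {
    paste0(attr(p, "genotype"), "_", attr(p, "timepoint"))
  }, character(1))
  m
}

#' Scale each variable by its maximum to a unit range
#'
#' Each column is divided by its maximum over the samples, so every variable
#' ends with maximum exactly 1 — the normalization used before the
#' correlation-matrix PCA.
#'
#' @param mat non-negative numeric matrix (samples x variables).
#' @return matrix of the same shape.
#' @export
normalize_unit_range <- function(mat) {
  .assert(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  .assert(all(mat >= 0), "values must be non-negative")
  mx <- apply(mat, 2, max)
  zero <- which(mx == 0)
  if (length(zero)) {
    stop(
      "all-zero variable(s): ",
      paste(colnames(mat)[zero] %||% zero, collapse = ", "),
      call. = FALSE
    )
  }
  sweep(mat, 2, mx, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal component analysis on the correlation matrix
#'
#' Eigen-decomposition of the correlation matrix of the (normalized)
#' phenoprint matrix; components are sorted by decreasing eigenvalue, sample
#' scores are the standardized data projected on the eigenvectors, and each
#' loading vector's sign is fixed so its largest-magnitude entry is positive
#' (reproducible biplots). Eigenvalues sum to the number of variables;
#' the score variance (n-1 denominator) along component k equals eigenvalue
#' k.
#'
#' @param mat numeric matrix (>= 3 samples, >= 2 variables with nonzero
#'   variance). Zero-variance variables are dropped with a warning.
#' @return object of class `qh_pca`: `eigenvalues`, `loadings`, `scores`,
#'   `prop_var`, `dropped`.
#' @export
pca_correlation <- function(mat) {
  .assert(is.matrix(mat) && nrow(mat) >= 3, "need at least 3 samples")
  v <- apply(mat, 2, stats::var)
  dropped <- colnames(mat)[v == 0] %||% which(v == 0)
  if (any(v == 0)) {
    warning("dropping zero-variance variable(s): ", paste(dropped, collapse = ", "))
    mat <- mat[, v > 0, drop = FALSE]
  }
  .assert(ncol(mat) >= 2, "need at least 2 variables with nonzero variance")
  ev <- eigen(stats::cor(mat), symmetric = TRUE)
  load <- ev$vectors
  flip <- apply(load, 2, function(col) sign(col[which.max(abs(col))]))
  load <- sweep(load, 2, flip, "*")
  rownames(load) <- colnames(mat)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  scores <- scale(mat) %*% load
  lam <- pmax(ev$values, 0)
  structure(
    list(
      eigenvalues = lam, loadings = load, scores = scores,
      prop_var = lam / sum(lam),
      dropped = if (any(v == 0)) dropped else character(0)
    ),
    class = "qh_pca"
  )
}

#' @export
print.qh_pca <- function(x, ...) {
  cat(
    "qh_pca:", length(x$eigenvalues), "components; PC1+PC2 explain",
    sprintf("%.1f%%\n", 100 * sum(x$prop_var[1:min(2, length(x$prop_var))]))
  )
  invisible(x)
}
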