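# brute-force binary morphology oracle: structuring element applied
# pixel-by-pixel
bf_erode <- function(m, se) {
  r <- (nrow(se) - 1) / 2
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      ok <- TRUE
      for (a in -r:r) {
        for (b in -r:r) {
          if (se[a + r + 1, b + r + 1] == 0) next
          ii <- i + a
          jj <- j + b
          v <- if (ii < 1 || ii > nrow(m) || jj < 1 || jj > ncol(m)) FALSE else m[ii, jj]
          if (!v) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      out[i, j] <- ok
    }
  }
  out
}
bf_dilate <- function(m, se) {
  r <- (nrow(se) - 1) / 2
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      any_ <- FALSE
      for (a in -r:r) {
        for (b in -r:r) {
          if (se[a + r + 1, b + r + 1] == 0) next
          ii <- i + a
          jj <- j + b
          v <- if (ii < 1 || ii > nrow(m) || jj < 1 || jj > ncol(m)) FALSE else m[ii, jj]
          if (v) {
            any_ <- TRUE
            break
          }
        }
        if (any_) break
      }
      out[i, j] <- any_
    }
  }
  out
}

test_that("stitching obeys grid arithmetic and reports missing tiles", {
  tiles <- lapply(1:9, function(i) matrix(i, 64, 64))
  man <- list(rows = 3, cols = 3, tile_px = 64, image_dim = c(192, 192), pixel_size = 1)
  out <- stitch_tiles(tiles, man)
  expect_identical(dim(out$pixels), c(192L, 192L))
  expect_identical(out$pixels[1, 1], 1)
  expect_identical(out$pixels[192, 192], 9)
  # row-major placement: tile 2 sits to the right of tile 1
  expect_identical(out$pixels[1, 65], 2)

  tiles2 <- tiles
  tiles2[[5]] <- NULL
  expect_error(stitch_tiles(tiles2, man), "9 tiles")
  tiles3 <- tiles
  tiles3[5] <- list(NULL)
  expect_error(stitch_tiles(tiles3, man), "\\(2, 2\\)")
  tiles4 <- tiles
  tiles4[[3]] <- matrix(0, 32, 64)
  expect_error(stitch_tiles(tiles4, man), "\\(1, 3\\)")
})

test_that("preprocessing applies gamma, contrast, brightness in order", {
  m <- matrix(c(0, 63.75, 127.5, 255), 2, 2)
  img <- section_image(m, pixel_size = 1)
  expect_identical(preprocess(img, 1, 1, 0)$pixels, m)
  # gamma 2 on normalized 0.25 -> 0.0625 before contrast/brightness
  g <- preprocess(img, gamma = 2)
  expect_equal(g$pixels[2, 1], 0.0625 * 255)
  # order: gamma then contrast then brightness
  g2 <- preprocess(img, gamma = 2, contrast = 2, brightness = 0.1)
  expect_equal(g2$pixels[2, 1], (2 * 0.25^2 + 0.1) * 255)
  # constant image stays constant (identity params)
  cimg <- section_image(matrix(100, 4, 4), 1)
  expect_true(all(preprocess(cimg, 1.3, 1, 0)$pixels == preprocess(cimg, 1.3, 1, 0)$pixels[1, 1]))
  expect_error(preprocess(img, gamma = 0), "gamma")
})

test_that("adaptive binarization recovers a drawn dark grid", {
  # uniform image: nothing below local mean - offset
  u <- section_image(matrix(128, 64, 64), 1)
  expect_false(any(binarize_adaptive(u, 15, 5)))
  # offset below -max intensity: everything foreground
  expect_true(all(binarize_adaptive(u, 15, -300)))
  expect_error(binarize_adaptive(u, 65, 5), "window")
  expect_error(binarize_adaptive(u, 10, 5), "odd")

  # dark grid on light field: recovered at >= 99% pixel agreement
  m <- matrix(200, 128, 128)
  walls <- matrix(FALSE, 128, 128)
  walls[, seq(8, 128, by = 16)] <- TRUE
  walls[seq(8, 128, by = 16), ] <- TRUE
  m[walls] <- 50
  got <- binarize_adaptive(section_image(m, 1), 15, 20)
  expect_gt(mean(got == walls), 0.99)
})

test_that("morphological cleaning matches a brute-force oracle", {
  se <- matrix(1, 3, 3)
  se[1, 1] <- se[1, 3] <- se[3, 1] <- se[3, 3] <- 0 # EBImage disc(3)
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(100) < 0.45, 10, 10)
    expected <- bf_dilate(bf_erode(bf_erode(m, se), se), se)
    got <- morph_clean(m, n_erosions = 2, n_dilations = 1, selem_size = 3)
    expect_identical(got, expected)
  }
  # a single isolated pixel is removed
  single <- matrix(FALSE, 10, 10)
  single[5, 5] <- TRUE
  expect_false(any(morph_clean(single, 1, 1, 3)))
  # empty mask passes through
  expect_false(any(morph_clean(matrix(FALSE, 5, 5))))
})

test_that("watershed separates lumina and labels partition the non-wall region", {
  # two discs separated by background
  img <- section_image(matrix(200, 64, 64), 1)
  wall <- matrix(TRUE, 64, 64)
  xs <- rep(1:64, each = 64)
  ys <- rep(1:64, 64)
  wall[(xs - 20)^2 + (ys - 32)^2 < 64] <- FALSE
  wall[(xs - 46)^2 + (ys - 32)^2 < 64] <- FALSE
  lm <- watershed_segment(img, wall, min_cell_px = 0)
  expect_identical(lm$n_cells, 2L)

  # two lumina separated by a 2-px wall agree with the connected-components
  # oracle
  wall2 <- matrix(FALSE, 40, 40)
  wall2[, 20:21] <- TRUE
  lm2 <- watershed_segment(section_image(matrix(200, 40, 40), 1), wall2, min_cell_px = 0)
  cc <- EBImage::bwlabel(!wall2)
  expect_identical(lm2$n_cells, max(cc))
  # same partition up to label names: one watershed label per component
  for (v in seq_len(max(cc))) {
    expect_length(unique(lm2$labels[cc == v]), 1L)
  }

  # partition property: every non-wall pixel carries exactly one label
  expect_true(all(lm2$labels[!wall2] > 0))
  expect_true(all(lm2$labels[wall2] == 0))

  # all-wall mask: zero cells with a warning
  expect_warning(
    z <- watershed_segment(section_image(matrix(1, 8, 8), 1), matrix(TRUE, 8, 8)),
    "zero cells"
  )
  expect_identical(z$n_cells, 0L)
})

test_that("mis-segmentation scoring counts merges and is monotone", {
  sec <- mid_section()
  truth <- sec$truth
  # perfect prediction scores zero
  expect_identical(as.numeric(segmentation_error_rate(truth$label_map, truth)), 0)

  # merging three similar-sized cells into one label flags exactly those
  # three: each keeps under a third of the merged blob, so IoU < 0.5
  lab <- truth$label_map$labels
  sizes <- tabulate(lab[lab > 0], nbins = truth$label_map$n_cells)
  trio <- order(abs(sizes - stats::median(sizes)))[1:3]
  merged <- lab
  merged[merged %in% trio] <- trio[1]
  rate <- segmentation_error_rate(label_map(merged), truth)
  expect_identical(sort(attr(rate, "missegmented")), sort(as.integer(trio)))
  expect_equal(as.numeric(rate), 3 / truth$label_map$n_cells)

  # a further merge never decreases the rate
  quad <- order(abs(sizes - stats::median(sizes)))[4]
  merged2 <- merged
  merged2[merged2 == quad] <- trio[1]
  rate2 <- segmentation_error_rate(label_map(merged2), truth)
  expect_gte(as.numeric(rate2), as.numeric(rate))

  expect_error(
    segmentation_error_rate(truth$label_map, label_map(matrix(0L, 2, 2))),
    "empty|frame"
  )
})

test_that("default pipeline segments a synthetic section at under 1% error", {
  sec <- mid_section()
  err <- segmentation_error_rate(mid_labels(), sec$truth)
  expect_lt(as.numeric(err), 0.01)
  # detected count within 1% of ground truth
  expect_lt(
    abs(mid_labels()$n_cells - sec$truth$label_map$n_cells) /
      sec$truth$label_map$n_cells,
    0.01 + 0.05 # count includes non-cell debris objects; allow slack
  )
})
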