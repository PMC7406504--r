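test_that("grid alignment ignores the nodata sentinel only", {
  a <- grid_spec(10, 10, 100)
  expect_true(grids_aligned(a, grid_spec(10, 10, 100, nodata = -1L)))
  expect_false(grids_aligned(a, grid_spec(10, 10, 50)))
  expect_false(grids_aligned(a, grid_spec(10, 10, 100, origin_x = 5)))
})

test_that("nearest-neighbour resampling onto the source grid is the identity", {
  g <- grid_spec(5, 4, 100)
  lay <- categorical_layer(g, matrix(sample(c(NA, 1:3), 20, TRUE), 5, 4), "synthetic")
  out <- resample_nearest(lay, g)
  expect_identical(out$data, lay$data)
  cont <- continuous_layer(g, matrix(runif(20), 5, 4))
  expect_identical(resample_nearest(cont, g)$data, cont$data)
})

test_that("upsampling to half the cell size replicates each source cell as a 2x2 block", {
  src_g <- grid_spec(2, 2, 200)
  src <- categorical_layer(src_g, matrix(c(1L, 3L, 2L, 4L), 2, 2), "synthetic")
  tgt <- grid_spec(4, 4, 100, origin_x = 0, origin_y = src_g$origin_y)
  out <- resample_nearest(src, tgt)
  # hand enumeration of target centers vs nearest source centers
  expected <- src$data[c(1, 1, 2, 2), c(1, 1, 2, 2)]
  dimnames(expected) <- NULL
  expect_identical(out$data, expected)
})

test_that("downsampling picks the source cell containing the coarse cell center", {
  src_g <- grid_spec(4, 4, 100)
  src <- categorical_layer(src_g, matrix(1:16, 4, 4), "synthetic")
  tgt <- grid_spec(2, 2, 200, origin_x = 0, origin_y = src_g$origin_y)
  out <- resample_nearest(src, tgt)
  # coarse centers fall on fine-cell boundaries; half-open cells put them in
  # fine rows/cols {2, 4} (hand enumeration)
  expected <- src$data[c(2, 4), c(2, 4)]
  dimnames(expected) <- NULL
  expect_identical(out$data, expected)
})

test_that("resampling disjoint extents errors and off-extent cells become nodata", {
  src <- categorical_layer(grid_spec(3, 3, 100), matrix(1L, 3, 3), "synthetic")
  far <- grid_spec(3, 3, 100, origin_x = 5000, origin_y = 5000)
  expect_error(resample_nearest(src, far), "overlap")
  wider <- grid_spec(3, 6, 100, origin_y = src$grid$origin_y)
  out <- resample_nearest(src, wider)
  expect_true(all(is.na(out$data[, 4:6])))
  expect_true(all(out$data[, 1:3] == 1L))
})

test_that("modal filter matches hand-counted windows, ties break small, nodata-only windows stay nodata", {
  g3 <- grid_spec(3, 3, 100)
  lay <- categorical_layer(g3, matrix(c(1L, 1L, 2L, 1L, 2L, 2L, 2L, 2L, 2L),
                                      3, 3, byrow = TRUE), "synthetic")
  out <- modal_filter(lay, 1)
  expect_identical(out$data[2, 2], 2L)   # five 2s vs four 1s
  # constant raster unchanged at any radius
  uni <- categorical_layer(g3, matrix(7L, 3, 3), "synthetic")
  expect_identical(modal_filter(uni, 2)$data, uni$data)
  # tie {4: 3, 7: 3} in a window -> 4
  tie <- categorical_layer(g3, matrix(c(4L, 4L, 4L, 7L, 7L, 7L, NA, NA, NA),
                                      3, 3, byrow = TRUE), "synthetic")
  expect_identical(modal_filter(tie, 2)$data[2, 2], 4L)
  # all-nodata window -> nodata
  empty <- categorical_layer(g3, matrix(NA_integer_, 3, 3), "synthetic")
  expect_true(all(is.na(modal_filter(empty, 1)$data)))
  expect_error(modal_filter(lay, 0), "radius")
})

test_that("modal filter equals the brute-force window oracle on random rasters", {
  set.seed(41)
  for (k in 1:25) {
    lay <- random_categorical(nr = 15, nc = 15, na_frac = 0.15)
    r <- sample(1:3, 1)
    expect_identical(modal_filter(lay, r)$data, oracle_modal(lay$data, r))
  }
})

test_that("dilation produces the exact Euclidean neighbourhoods", {
  g <- grid_spec(9, 9, 100)
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  m <- binary_mask(g, one)
  # radius = cell size: plus-shape (diagonals at sqrt(2)*cell excluded)
  plus <- binary_dilate(m, 100)
  expect_identical(sum(plus$data), 5L)
  expect_true(all(plus$data[cbind(c(5, 4, 6, 5, 5), c(5, 5, 5, 4, 6))]))
  # radius 3 cells -> 29-cell disk
  expect_identical(sum(binary_dilate(m, 300)$data), 29L)
  # empty mask stays empty
  expect_identical(sum(binary_dilate(binary_mask(g, matrix(FALSE, 9, 9)), 300)$data), 0L)
})

test_that("dilation is monotone and always contains its input", {
  set.seed(42)
  for (k in 1:10) {
    g <- grid_spec(12, 12, 100)
    a <- matrix(runif(144) < 0.1, 12, 12)
    b <- a | matrix(runif(144) < 0.1, 12, 12)   # a subset of b
    r <- runif(1, 50, 450)
    da <- binary_dilate(binary_mask(g, a), r)$data
    db <- binary_dilate(binary_mask(g, b), r)$data
    expect_true(all(da[a]))          # contains input
    expect_true(all(db[da]))         # monotone
  }
})

test_that("dilation equals the union of per-cell disks", {
  set.seed(43)
  g <- grid_spec(10, 10, 100)
  flags <- matrix(runif(100) < 0.12, 10, 10)
  m <- binary_mask(g, flags)
  for (r in c(100, 250, 300)) {
    manual <- matrix(FALSE, 10, 10)
    for (idx in which(flags)) {
      rc <- arrayInd(idx, c(10, 10))
      manual[disk_cells(g, rc[1], rc[2], r)] <- TRUE
    }
    expect_identical(binary_dilate(m, r)$data, manual)
  }
})

test_that("disk_cells clips at edges and degenerates to the center cell", {
  g <- grid_spec(8, 8, 100)
  expect_identical(disk_cells(g, 4, 4, 50), cbind(row = 4L, col = 4L))
  corner <- disk_cells(g, 1, 1, 100)
  expect_identical(nrow(corner), 3L)   # center + right + below
  expect_identical(nrow(disk_cells(g, 4, 4, 300)), 29L)
  expect_error(disk_cells(g, 0, 4, 100), "outside")
  expect_error(disk_cells(g, 4, 9, 100), "outside")
})
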