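make_const_layers <- function(nr = 4, nc = 4) {
  g <- grid_spec(nr, nc, 100)
  list(g = g,
       zero = continuous_layer(g, matrix(0, nr, nc), "heads/km2"),
       region = categorical_layer(g, matrix(1L, nr, nc), "livestock_region"))
}

test_that("LSU density multiplies heads by region factors and sums species", {
  cl <- make_const_layers()
  factors <- lsu_factor_table()
  heads <- list(cattle = cl$zero, sheep = cl$zero)
  expect_true(all(lsu_density(heads, factors, cl$region)$data == 0))
  cattle2 <- continuous_layer(cl$g, matrix(2, 4, 4), "heads/km2")
  out <- lsu_density(list(cattle = cattle2, sheep = cl$zero), factors, cl$region)
  expect_equal(out$data[1, 1], 1.4)             # 2.0 heads x 0.7
  mix <- lsu_density(list(cattle = continuous_layer(cl$g, matrix(1, 4, 4)),
                          sheep = continuous_layer(cl$g, matrix(3, 4, 4))),
                     factors, cl$region)
  expect_equal(mix$data[2, 2], 1.0)             # 1x0.7 + 3x0.1
})

test_that("LSU density treats species nodata as zero heads and errors on missing factors", {
  cl <- make_const_layers()
  factors <- lsu_factor_table()
  half_na <- matrix(2, 4, 4); half_na[1, ] <- NA
  out <- lsu_density(list(cattle = continuous_layer(cl$g, half_na),
                          sheep = continuous_layer(cl$g, matrix(3, 4, 4))),
                     factors, cl$region)
  expect_equal(out$data[1, 1], 0.3)   # cattle NA -> 0, sheep only
  expect_equal(out$data[2, 1], 1.7)
  all_na <- continuous_layer(cl$g, matrix(NA_real_, 4, 4))
  out2 <- lsu_density(list(cattle = all_na), factors, cl$region)
  expect_true(all(is.na(out2$data)))
  region9 <- categorical_layer(cl$g, matrix(9L, 4, 4), "livestock_region")
  expect_error(lsu_density(list(cattle = continuous_layer(cl$g, matrix(1, 4, 4))),
                           factors, region9),
               "cattle.*region 9")
})

test_that("LSU density is linear in head counts", {
  set.seed(11)
  cl <- make_const_layers(6, 6)
  factors <- lsu_factor_table()
  h1 <- list(cattle = continuous_layer(cl$g, matrix(runif(36, 0, 5), 6, 6)),
             goats = continuous_layer(cl$g, matrix(runif(36, 0, 9), 6, 6)))
  h2 <- lapply(h1, function(l) continuous_layer(l$grid, l$data * 2, l$units))
  expect_equal(lsu_density(h2, factors, cl$region)$data,
               2 * lsu_density(h1, factors, cl$region)$data)
})

pasture_fixture <- function(lsu_val, lc_code = 30L, koppen_code = 6L,
                            excluded = FALSE) {
  g <- grid_spec(2, 2, 100)
  list(lc = categorical_layer(g, matrix(lc_code, 2, 2), "land_cover"),
       lsu = continuous_layer(g, matrix(lsu_val, 2, 2), "LSU/km2"),
       excl = binary_mask(g, matrix(excluded, 2, 2)),
       kop = categorical_layer(g, matrix(koppen_code, 2, 2), "koppen"))
}

test_that("pasture mask applies all four conditions with an inclusive LSU threshold", {
  fx <- pasture_fixture(1.5)
  expect_true(all(pasture_mask(fx$lc, fx$lsu, fx$excl, fx$kop)$data))
  # the 1 LSU/km2 boundary is included; just below is excluded
  expect_true(all(pasture_mask(pasture_fixture(1.0)$lc, pasture_fixture(1.0)$lsu,
                               fx$excl, fx$kop)$data))
  expect_false(any(pasture_mask(fx$lc, pasture_fixture(0.999)$lsu,
                                fx$excl, fx$kop)$data))
  # tree cover fails regardless of stocking
  tree <- pasture_fixture(10, lc_code = 10L)
  expect_false(any(pasture_mask(tree$lc, tree$lsu, tree$excl, tree$kop)$data))
  # grass/steppe ecoregion exclusion and non-forest climate both veto
  expect_false(any(pasture_mask(fx$lc, fx$lsu,
                                binary_mask(fx$lc$grid, matrix(TRUE, 2, 2)),
                                fx$kop)$data))
  arid <- pasture_fixture(1.5, koppen_code = 4L)
  expect_false(any(pasture_mask(arid$lc, arid$lsu, arid$excl, arid$kop)$data))
})

test_that("raising the LSU threshold never adds pasture cells", {
  set.seed(12)
  g <- grid_spec(10, 10, 100)
  lc <- categorical_layer(g, matrix(sample(c(10L, 20L, 30L), 100, TRUE), 10, 10),
                          "land_cover")
  lsu <- continuous_layer(g, matrix(runif(100, 0, 3), 10, 10), "LSU/km2")
  excl <- binary_mask(g, matrix(runif(100) < 0.2, 10, 10))
  kop <- categorical_layer(g, matrix(sample(c(4L, 6L), 100, TRUE), 10, 10), "koppen")
  prev <- NULL
  for (thr in c(0.5, 1, 1.5, 2.5)) {
    cur <- pasture_mask(lc, lsu, excl, kop, pasture_params(lsu_threshold = thr))$data
    expect_true(all(cur[cur] %in% TRUE))
    expect_true(all((!is.na(lc$data) & lc$data %in% c(20L, 30L))[cur]))
    if (!is.null(prev)) expect_true(all(prev[cur]))   # cur subset of prev
    prev <- cur
  }
})

test_that("rural gardens require very small arable fields inside the urban buffer", {
  g <- grid_spec(11, 21, 100)
  lc <- matrix(40L, 11, 21)          # arable everywhere ...
  lc[6, 6] <- 50L                    # ... except one urban cell
  fs <- matrix(1L, 11, 21)           # very small fields everywhere
  lcl <- categorical_layer(g, lc, "land_cover")
  fsl <- categorical_layer(g, fs, "field_size")
  out <- rural_gardens_mask(lcl, fsl, buffer_m = 500)
  expect_true(out$data[6, 9])        # 300 m from urban
  expect_true(out$data[6, 11])       # exactly 500 m: included
  expect_false(out$data[6, 14])      # 800 m: outside
  expect_false(out$data[6, 6])       # the urban cell itself is never a garden
  # large fields or non-arable cover are excluded even adjacent to urban
  fs_large <- categorical_layer(g, matrix(4L, 11, 21), "field_size")
  expect_false(any(rural_gardens_mask(lcl, fs_large)$data))
  # no urban anywhere -> empty mask
  no_urban <- categorical_layer(g, matrix(40L, 11, 21), "land_cover")
  expect_false(any(rural_gardens_mask(no_urban, fsl)$data))
  # shrinking the buffer never adds cells
  smaller <- rural_gardens_mask(lcl, fsl, buffer_m = 300)$data
  expect_true(all(out$data[smaller]))
})

test_that("plantation mask is membership of the managed-forest classes", {
  g <- grid_spec(2, 3, 100)
  mgmt <- categorical_layer(g, matrix(c(1L, 2L, 3L, 4L, 5L, NA), 2, 3),
                            "forest_management")
  out <- plantation_mask(mgmt)
  expect_identical(as.vector(out$data), c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("wetland expansion grows outward without relabelling wetlands", {
  g <- grid_spec(5, 5, 100)
  wet <- matrix(NA_integer_, 5, 5); wet[3, 3] <- 3L
  lay <- categorical_layer(g, wet, "wetland")
  out <- expand_wetlands(lay, radius_cells = 1)
  # neighbours whose window contains the single wetland cell acquire its code
  expect_true(all(out$data[2:4, 2:4] == 3L))
  expect_true(all(is.na(out$data[1, ])))
  # no wetland codes -> unchanged
  none <- categorical_layer(g, matrix(NA_integer_, 5, 5), "wetland")
  expect_identical(expand_wetlands(none, 2)$data, none$data)
  # labelled wetland cells never change; wetland area never shrinks
  set.seed(13)
  mixed <- matrix(sample(c(NA, NA, NA, 1L, 3L, 5L), 25, TRUE), 5, 5)
  ml <- categorical_layer(g, mixed, "wetland")
  grown <- expand_wetlands(ml, 1)
  keep <- !is.na(mixed)
  expect_identical(grown$data[keep], mixed[keep])
  expect_gte(sum(!is.na(grown$data)), sum(keep))
})

test_that("montane split is mask OR optional elevation threshold", {
  g <- grid_spec(1, 3, 100)
  mtn <- binary_mask(g, matrix(c(TRUE, FALSE, FALSE), 1, 3))
  elev <- continuous_layer(g, matrix(c(100, 2500, 2500), 1, 3), "m")
  with_thr <- mountain_split(mtn, elev, threshold_m = 1500)
  expect_identical(as.vector(with_thr$data), c(TRUE, TRUE, TRUE))
  without <- mountain_split(mtn, elev, threshold_m = NULL)
  expect_identical(as.vector(without$data), c(TRUE, FALSE, FALSE))
})

test_that("tropics mask is plain code membership with nodata unset", {
  g <- grid_spec(1, 4, 100)
  biome <- categorical_layer(g, matrix(c(1L, 2L, 4L, NA), 1, 4), "biome")
  expect_identical(as.vector(tropics_mask(biome, c(1L, 4L))$data),
                   c(TRUE, FALSE, TRUE, FALSE))
  expect_false(any(tropics_mask(biome, integer(0))$data))
})
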