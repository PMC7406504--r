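# Seeded generator of internally consistent input stacks with known truth.
#
# Truth-first construction: a patchy ground-truth habitat map is sampled
# first, then every input layer is derived so that, at each cell, the truth
# class's rule in the default ruleset holds and every earlier rule fails.
# classify() on the generated stack therefore reproduces the truth exactly,
# giving the classifier an exact oracle.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default areal class mix of the synthetic world
#'
#' Target proportions per habitat code, a forest-dominated mix spanning
#' every class the default ruleset can emit. Sums to 0.99; the remaining 1%
#' of cells are nodata (unmapped, e.g. sea).
#' @return Named numeric vector (names are habitat codes).
#' @export
default_class_mix <- function() {
  c(`106` = 0.125, `109` = 0.05, `107` = 0.01, `108` = 0.02, `104` = 0.10,
    `101` = 0.07, `100` = 0.03, `200` = 0.08, `304` = 0.05, `300` = 0.04,
    `404` = 0.07, `400` = 0.03, `504` = 0.03, `503` = 0.015, `505` = 0.015,
    `500` = 0.02, `600` = 0.03, `801` = 0.04, `803` = 0.02, `800` = 0.02,
    `1401` = 0.04, `1402` = 0.04, `1403` = 0.02, `1404` = 0.01,
    `1405` = 0.015)
}

#' Synthetic-world parameters
#'
#' @param seed integer RNG seed; every generator output is a pure function
#'   of its parameters and this seed.
#' @param n_rows,n_cols grid dimensions (default 200 x 200).
#' @param cell_size cell side in metres (default 100, the working
#'   resolution of the fine habitat map).
#' @param patch_scale expected patch diameter in cells; controls the seed
#'   density of the tessellation (default 8).
#' @param class_mix named target areal proportions by habitat code, summing
#'   to at most 1 (remainder becomes nodata).
#' @param record_noise list with `displacement_sd_m` (isotropic positional
#'   error SD) and `mislabel_rate` (probability a record's expected class is
#'   replaced by a uniformly random other mapped class).
#' @param pasture_fraction share of LSU-eligible cells actually pushed over
#'   the pasture threshold; tessellated pasture cells failing the draw are
#'   relabelled temperate grassland so the truth map stays exact.
#' @return A list of class `world_params`.
#' @export
world_params <- function(seed = 1L, n_rows = 200, n_cols = 200,
                         cell_size = 100, patch_scale = 8,
                         class_mix = default_class_mix(),
                         record_noise = list(displacement_sd_m = 0,
                                             mislabel_rate = 0),
                         pasture_fraction = 1) {
  stopifnot(all(class_mix >= 0), sum(class_mix) <= 1 + 1e-12,
            patch_scale >= 1, pasture_fraction >= 0, pasture_fraction <= 1,
            record_noise$mislabel_rate >= 0, record_noise$mislabel_rate < 1)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), cell_size = cell_size,
                 patch_scale = patch_scale, class_mix = class_mix,
                 record_noise = record_noise,
                 pasture_fraction = pasture_fraction),
            class = "world_params")
}

# Per-class input-layer attributes. Each row fixes the layer values a truth
# cell of that class receives; chosen so the class's own rule holds and all
# earlier rules of the default ruleset fail (e.g. a 106 cell gets tropical
# climate but no montane flag so 109 cannot fire first).
world_attribute_table <- function() {
  A <- function(code, lc, kop, biome, montane = FALSE, wet = NA_integer_,
                field = 4L, mgmt = NA_integer_, mangrove = FALSE)
    data.frame(code = code, lc = lc, kop = kop, biome = biome,
               montane = montane, wet = wet, field = field, mgmt = mgmt,
               mangrove = mangrove)
  rbind(
    A(100,  10L, 10L, 2L, mgmt = 1L),
    A(101,  10L,  8L, 2L, mgmt = 1L),
    A(104,  10L,  6L, 2L, mgmt = 1L),
    A(106,  10L,  2L, 1L, mgmt = 1L),
    A(107,  10L,  1L, 1L, mgmt = 1L, mangrove = TRUE),
    A(108,  10L,  1L, 1L, mgmt = 1L, wet = 4L),
    A(109,  10L,  1L, 1L, mgmt = 1L, montane = TRUE),
    A(200,  30L,  3L, 4L),
    A(300,  20L,  4L, 2L),
    A(304,  20L,  6L, 2L),
    A(400,  30L, 10L, 3L),
    A(404,  30L,  6L, 3L),
    A(500,  70L,  6L, 2L, wet = 2L),
    A(503,  80L,  6L, 2L, wet = 5L),
    A(504,  80L,  6L, 2L, wet = 3L),
    A(505,  70L,  6L, 2L, wet = 1L),
    A(600,  60L,  6L, 2L, montane = TRUE),
    A(800,  60L, 10L, 2L),
    A(801,  60L,  4L, 2L),
    A(803,  60L,  5L, 2L),
    A(1401, 40L,  6L, 2L),
    A(1402, 30L,  6L, 2L),
    A(1403, 10L,  6L, 2L, mgmt = 3L),
    A(1404, 40L,  6L, 2L, field = 1L),
    A(1405, 50L,  6L, 2L)
  )
}

# Patchy tessellation: seed points carry codes sampled by class_mix; each
# cell joins its nearest seed (ties to the smallest seed index).
tessellate_truth <- function(p) {
  n_cells <- p$n_rows * p$n_cols
  k <- max(length(p$class_mix), round(n_cells / p$patch_scale^2))
  sr <- sample.int(p$n_rows, k, replace = TRUE)
  sc <- sample.int(p$n_cols, k, replace = TRUE)
  codes <- as.integer(names(p$class_mix))
  p_nodata <- max(0, 1 - sum(p$class_mix))
  draw <- sample(c(codes, NA_integer_), k, replace = TRUE,
                 prob = c(p$class_mix, p_nodata))
  t_mat <- matrix(NA_integer_, p$n_rows, p$n_cols)
  col_sq <- outer(sc, seq_len(p$n_cols), function(s, j) (j - s)^2)
  for (i in seq_len(p$n_rows)) {
    d2 <- col_sq + (i - sr)^2
    t_mat[i, ] <- draw[max.col(-t(d2), ties.method = "first")]
  }
  t_mat
}

#' Generate a synthetic world: truth habitat map plus input stack
#'
#' Samples a patchy ground-truth map (seeded nearest-seed tessellation) and
#' derives every input layer so that [classify()] with the default ruleset
#' reproduces the truth on every non-nodata cell — the module's defining
#' contract. Derived masks (pasture, plantation, rural gardens, montane,
#' tropics, ecoregion exclusion) are built by the real mask builders from
#' the generated base layers, so the geometric constructions are exercised
#' end to end; rural-garden patches are planted with a nearby urban cell
#' (or relabelled arable) so the 500 m buffer geometry holds exactly.
#'
#' @param params a [world_params()].
#' @return List with `truth` (`categorical_layer` of habitat codes),
#'   `stack` (`layer_stack` of all base and derived layers) and `params`.
#' @export
generate_world <- function(params = world_params()) {
  stopifnot(inherits(params, "world_params"))
  att <- world_attribute_table()
  codes <- as.integer(names(params$class_mix))
  unknown <- setdiff(codes, att$code)
  rs_targets <- vapply(default_ruleset()$rules, function(r) r$target, integer(1))
  unreachable <- setdiff(codes, rs_targets)
  if (length(unknown) || length(unreachable))
    stop("class_mix code(s) not producible by the default ruleset: ",
         paste(union(unknown, unreachable), collapse = ", "))
  with_seed(params$seed, {
    g <- grid_spec(params$n_rows, params$n_cols, cell_size = params$cell_size)
    t_mat <- tessellate_truth(params)

    # pasture_fraction: pasture cells failing the draw become grassland
    if (params$pasture_fraction < 1) {
      pc <- which(t_mat == 1402L)
      demote <- pc[stats::runif(length(pc)) > params$pasture_fraction]
      t_mat[demote] <- 404L
    }

    # Rural gardens need an urban cell within 500 m: plant urban seeds into
    # uncovered garden patches, then relabel still-uncovered cells arable.
    buffer_m <- 500
    if (any(t_mat == 1404L, na.rm = TRUE)) {
      repeat {
        urban <- binary_mask(g, !is.na(t_mat) & t_mat == 1405L)
        covered <- if (any(urban$data)) binary_dilate(urban, buffer_m)$data
                   else matrix(FALSE, g$n_rows, g$n_cols)
        open <- which(!is.na(t_mat) & t_mat == 1404L & !covered)
        if (length(open) == 0) break
        t_mat[open[1]] <- 1405L   # smallest linear index: deterministic
      }
    }

    idx <- match(t_mat, att$code)
    lay_cat <- function(vals, legend) {
      m <- matrix(vals[idx], g$n_rows, g$n_cols)
      categorical_layer(g, m, legend)
    }
    land_cover <- lay_cat(att$lc, "land_cover")
    koppen <- lay_cat(att$kop, "koppen")
    biome <- lay_cat(att$biome, "biome")
    wetlands <- lay_cat(att$wet, "wetland")
    field_size <- lay_cat(att$field, "field_size")
    forest_mgmt <- lay_cat(att$mgmt, "forest_management")
    mountain <- binary_mask(g, matrix(att$montane[idx] %in% TRUE,
                                      g$n_rows, g$n_cols))
    mangrove <- binary_mask(g, matrix(att$mangrove[idx] %in% TRUE,
                                      g$n_rows, g$n_cols))
    elevation <- continuous_layer(
      g, matrix(ifelse(is.na(t_mat), NA_real_,
                       200 + 1800 * (att$montane[idx] %in% TRUE)) +
                  stats::runif(length(t_mat), 0, 50),
                g$n_rows, g$n_cols), units = "m")
    region <- categorical_layer(
      g, matrix(ifelse(is.na(t_mat), NA_integer_, 1L), g$n_rows, g$n_cols),
      "livestock_region")

    # Livestock head counts: pasture truth cells carry cattle well over the
    # 1 LSU/km2 threshold; everything else is ungrazed.
    params_p <- pasture_params()
    is_pasture <- !is.na(t_mat) & t_mat == 1402L
    cattle_heads <- matrix(0, g$n_rows, g$n_cols)
    factors <- lsu_factor_table()
    f_cattle <- factors$factor[factors$species == "cattle" & factors$region == 1]
    cattle_heads[is_pasture] <-
      (params_p$lsu_threshold * stats::runif(sum(is_pasture), 1, 3)) / f_cattle
    cattle_heads[is.na(t_mat)] <- NA_real_
    zero <- matrix(0, g$n_rows, g$n_cols); zero[is.na(t_mat)] <- NA_real_
    heads <- list(cattle = continuous_layer(g, cattle_heads, "heads/km2"),
                  sheep = continuous_layer(g, zero, "heads/km2"),
                  goats = continuous_layer(g, zero, "heads/km2"),
                  horses = continuous_layer(g, zero, "heads/km2"),
                  buffalo = continuous_layer(g, zero, "heads/km2"))

    # Derived layers through the real builders.
    tropics <- tropics_mask(biome, c(1L, 4L))
    ecoregion_excluded <- tropics_mask(biome, c(3L, 4L))
    montane <- mountain_split(mountain, elevation, threshold_m = NULL)
    lsu <- lsu_density(heads, factors, region)
    pasture <- pasture_mask(land_cover, lsu, ecoregion_excluded, koppen,
                            params_p)
    plantation <- plantation_mask(forest_mgmt)
    rural_gardens <- rural_gardens_mask(land_cover, field_size,
                                        buffer_m = buffer_m)

    # Garden cells the buffer geometry cannot reach are arable by definition.
    still_garden <- !is.na(t_mat) & t_mat == 1404L
    t_mat[still_garden & !rural_gardens$data] <- 1401L

    stack <- layer_stack(
      land_cover = land_cover, koppen = koppen, biome = biome,
      elevation = elevation, mountain = mountain, mangrove = mangrove,
      wetlands = wetlands, field_size = field_size,
      forest_mgmt = forest_mgmt, region = region,
      cattle = heads$cattle, sheep = heads$sheep, goats = heads$goats,
      horses = heads$horses, buffalo = heads$buffalo,
      lsu = lsu, tropics = tropics,
      ecoregion_excluded = ecoregion_excluded, montane = montane,
      pasture = pasture, plantation = plantation,
      rural_gardens = rural_gardens)

    list(truth = categorical_layer(g, t_mat, "iucn_habitat"),
         stack = stack, params = params)
  })
}

#' Generate noisy occurrence records over a truth map
#'
#' Samples `n` cells uniformly over the non-nodata truth map (i.e. in
#' proportion to class areas), records the truth class as the specialist's
#' expected habitat, then applies the configured noise: mislabelling with
#' probability `mislabel_rate` to a uniformly random *other* mapped class,
#' isotropic positional displacement (SD `displacement_sd_m`, applied after
#' the expected class is captured, mimicking real positional error), stale
#' dates and excessive coordinate uncertainties at configurable rates. Each
#' species (one per habitat class) receives a rectangular range polygon
#' covering its records.
#'
#' @param world a [generate_world()] result (or a list with `truth` and
#'   `params`).
#' @param n number of records.
#' @param noise list with any of `displacement_sd_m`, `mislabel_rate`,
#'   `stale_date_rate`, `bad_uncertainty_rate` (defaults from
#'   `world$params$record_noise`, missing entries 0).
#' @param source_mix named sampling probabilities over record sources.
#' @param seed RNG seed (default derived from the world's seed).
#' @return List with `records` ([occurrence_records()]) and `ranges` (named
#'   list of rectangle vertex matrices by species).
#' @export
generate_records <- function(world, n,
                             noise = world$params$record_noise,
                             source_mix = c(gbif = 0.55, ebird = 0.25,
                                            predicts = 0.1, visual = 0.1),
                             seed = world$params$seed + 1L) {
  stopifnot(n >= 1)
  nz <- function(x) if (is.null(x)) 0 else x
  disp <- nz(noise$displacement_sd_m)
  eps <- nz(noise$mislabel_rate)
  stale <- nz(noise$stale_date_rate)
  badu <- nz(noise$bad_uncertainty_rate)
  truth <- world$truth
  g <- truth$grid
  with_seed(seed, {
    valid <- which(!is.na(truth$data))
    pick <- valid[sample.int(length(valid), n, replace = TRUE)]
    rc <- arrayInd(pick, dim(truth$data))
    true_code <- truth$data[pick]
    mapped <- sort(unique(as.vector(truth$data)))
    mapped <- mapped[!is.na(mapped)]
    expected <- true_code
    flip <- stats::runif(n) < eps
    if (any(flip) && length(mapped) > 1)
      expected[flip] <- vapply(true_code[flip], function(tc) {
        others <- setdiff(mapped, tc)
        others[sample.int(length(others), 1L)]
      }, integer(1))
    ctr <- cell_center(g, rc[, 1], rc[, 2])
    x <- ctr$x + stats::rnorm(n, 0, disp)
    y <- ctr$y + stats::rnorm(n, 0, disp)
    src <- sample(names(source_mix), n, replace = TRUE, prob = source_mix)
    dates <- as.Date("2005-01-01") +
      sample.int(as.integer(as.Date("2019-12-31") - as.Date("2005-01-01")),
                 n, replace = TRUE)
    is_stale <- stats::runif(n) < stale
    dates[is_stale] <- as.Date("2000-01-01") +
      sample.int(1500, sum(is_stale), replace = TRUE)
    unc <- rep(NA_real_, n)
    unc[src == "gbif"] <- stats::runif(sum(src == "gbif"), 5, 290)
    unc[src == "ebird"] <- stats::runif(sum(src == "ebird"), 1, 29)
    bad <- stats::runif(n) < badu
    unc[bad & src == "gbif"] <- stats::runif(sum(bad & src == "gbif"), 310, 2000)
    unc[bad & src == "ebird"] <- stats::runif(sum(bad & src == "ebird"), 35, 500)
    ext <- ifelse(src == "predicts", 100, NA_real_)
    recs <- occurrence_records(
      record_id = sprintf("rec%06d", seq_len(n)),
      species_id = sprintf("sp%d", expected),
      x = x, y = y, observed_date = dates, coord_uncertainty_m = unc,
      source = src, expected_code = expected, sampling_extent_m = ext)
    pad <- g$cell_size
    ranges <- lapply(split(seq_len(n), recs$species_id), function(i) {
      xr <- range(recs$x[i]) + c(-pad, pad)
      yr <- range(recs$y[i]) + c(-pad, pad)
      cbind(x = c(xr[1], xr[2], xr[2], xr[1], xr[1]),
            y = c(yr[1], yr[1], yr[2], yr[2], yr[1]))
    })
    list(records = recs, ranges = ranges)
  })
}

#' Generate rectangular validation polygons over a truth map
#'
#' Rectangles of `size_cells` x `size_cells` cells at uniform positions.
#' With probability `p_present` a polygon's `expected_code` is a class
#' actually present inside it, otherwise a mapped class absent from it (so
#' the polygon presence test is `TRUE`/`FALSE` by construction). Emulates
#' site-checklist (IBA-style) polygon validation.
#'
#' @param world a [generate_world()] result.
#' @param n number of polygons.
#' @param size_cells rectangle side length in cells.
#' @param p_present probability the expected class is present.
#' @param seed RNG seed.
#' @return Data frame with `polygon_id`, `expected_code`, `present_truth`,
#'   and a list-column `geometry` of vertex matrices.
#' @export
generate_polygons <- function(world, n, size_cells = 6, p_present = 0.9,
                              seed = world$params$seed + 2L) {
  truth <- world$truth
  g <- truth$grid
  stopifnot(n >= 1, size_cells >= 1, size_cells <= min(g$n_rows, g$n_cols))
  mapped <- sort(unique(as.vector(truth$data)))
  mapped <- mapped[!is.na(mapped)]
  with_seed(seed, {
    want_present <- stats::runif(n) < p_present
    expected <- integer(n); present <- logical(n)
    r0 <- integer(n); c0 <- integer(n)
    geoms <- vector("list", n)
    for (i in seq_len(n)) {
      # sites are drawn over mapped area: resample all-nodata rectangles
      for (attempt in 1:100) {
        r0[i] <- sample.int(g$n_rows - size_cells + 1L, 1L)
        c0[i] <- sample.int(g$n_cols - size_cells + 1L, 1L)
        block <- truth$data[r0[i]:(r0[i] + size_cells - 1L),
                            c0[i]:(c0[i] + size_cells - 1L)]
        if (any(!is.na(block))) break
      }
      inside <- sort(unique(as.vector(block)))
      inside <- inside[!is.na(inside)]
      absent <- setdiff(mapped, inside)
      use_present <- length(inside) > 0 &&
        (want_present[i] || length(absent) == 0)
      pool <- if (use_present) inside else absent
      expected[i] <- pool[sample.int(length(pool), 1L)]
      present[i] <- use_present
      # rectangle hugging the covered cells' outer edges
      x1 <- g$origin_x + (c0[i] - 1L) * g$cell_size
      x2 <- g$origin_x + (c0[i] - 1L + size_cells) * g$cell_size
      y1 <- g$origin_y - (r0[i] - 1L + size_cells) * g$cell_size
      y2 <- g$origin_y - (r0[i] - 1L) * g$cell_size
      geoms[[i]] <- cbind(x = c(x1, x2, x2, x1, x1),
                          y = c(y1, y1, y2, y2, y1))
    }
    out <- data.frame(polygon_id = sprintf("poly%05d", seq_len(n)),
                      expected_code = expected, present_truth = present)
    out$geometry <- geoms
    out
  })
}
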