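#' Livestock-unit conversion factors
#'
#' Head counts of grazing/browsing livestock (buffalo, cattle, goats,
#' horses, sheep) are converted to livestock units (LSU) with per-species,
#' per-region factors before thresholding for pastureland. The shipped table
#' (`extdata/lsu_factors.csv`) holds documented defaults for a single
#' region; factors are data, not code — supply a regionalised table for
#' production use.
#'
#' @param path CSV with columns `species`, `region`, `factor`.
#' @return Data frame of class `lsu_factor_table`.
#' @export
lsu_factor_table <- function(path = system.file("extdata", "lsu_factors.csv",
                                                package = "habitatmapr")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "region", "factor") %in% names(tab)),
            all(tab$factor > 0))
  tab$region <- as.integer(tab$region)
  class(tab) <- c("lsu_factor_table", "data.frame")
  tab
}

#' Cellwise livestock-unit density
#'
#' Sums `heads x factor(species, region)` over all species layers. Nodata in
#' a species layer counts as zero heads for that species; a cell with nodata
#' in every species layer is nodata. A head-count observed in a region with
#' no factor for that species is an error naming the missing pair.
#'
#' @param head_densities named list of `continuous_layer`s (heads/km2), one
#'   per species.
#' @param factors an [lsu_factor_table()].
#' @param region_layer `categorical_layer` of livestock-region codes.
#' @return `continuous_layer` of LSU/km2.
#' @export
lsu_density <- function(head_densities, factors, region_layer) {
  stopifnot(length(head_densities) >= 1, !is.null(names(head_densities)),
            inherits(region_layer, "categorical_layer"))
  g <- region_layer$grid
  total <- matrix(0, g$n_rows, g$n_cols)
  all_na <- matrix(TRUE, g$n_rows, g$n_cols)
  region <- region_layer$data
  for (sp in names(head_densities)) {
    lay <- head_densities[[sp]]
    stopifnot(inherits(lay, "continuous_layer"))
    if (!grids_aligned(lay$grid, g))
      stop("head-density layer '", sp, "' is not aligned with the region layer")
    heads <- lay$data
    frows <- factors[factors$species == sp, , drop = FALSE]
    fmap <- frows$factor[match(region, frows$region)]
    missing_pair <- !is.na(heads) & heads > 0 & !is.na(region) & is.na(fmap)
    if (any(missing_pair)) {
      reg <- unique(region[missing_pair])
      stop("no LSU factor for (", sp, ", region ", reg[1], ")")
    }
    contrib <- heads * fmap
    contrib[is.na(contrib)] <- 0
    total <- total + contrib
    all_na <- all_na & is.na(heads)
  }
  total[all_na] <- NA_real_
  continuous_layer(g, total, units = "LSU/km2")
}

#' Pastureland parameters
#'
#' The pastureland definition: non-tree-covered vegetation carrying at least
#' `lsu_threshold` LSU/km2 on land climatically suitable for forest cover
#' (where trees would grow absent grazing), excluding grass/tundra/steppe/
#' meadow-defined ecoregions.
#'
#' @param lsu_threshold LSU/km2 boundary, inclusive (default 1.0).
#' @param nontree_lc_codes land-cover codes counted as non-tree vegetation
#'   (defaults follow the shipped legend: shrub 20, herbaceous 30,
#'   bare/sparse 60).
#' @param forest_climate_groups Koeppen major groups suitable for forest.
#' @return A list of class `pasture_params`.
#' @export
pasture_params <- function(lsu_threshold = 1.0,
                           nontree_lc_codes = c(20L, 30L, 60L),
                           forest_climate_groups = c("Tropical", "Temperate",
                                                     "Continental")) {
  stopifnot(lsu_threshold > 0, length(nontree_lc_codes) >= 1,
            length(forest_climate_groups) >= 1)
  structure(list(lsu_threshold = lsu_threshold,
                 nontree_lc_codes = as.integer(nontree_lc_codes),
                 forest_climate_groups = forest_climate_groups),
            class = "pasture_params")
}

#' Pastureland mask
#'
#' A cell is pasture iff its land cover is non-tree vegetation, its LSU
#' density reaches the threshold (inclusive), it is not in an excluded
#' (grass/steppe-type) ecoregion, and its climate group is forest-suitable.
#' Nodata in any condition leaves the cell unset.
#'
#' @param land_cover `categorical_layer`.
#' @param lsu `continuous_layer` of LSU/km2 (see [lsu_density()]).
#' @param ecoregion_excluded `binary_mask` of excluded ecoregions.
#' @param koppen `categorical_layer` of climate-zone codes.
#' @param params a [pasture_params()].
#' @return `binary_mask`.
#' @export
pasture_mask <- function(land_cover, lsu, ecoregion_excluded, koppen,
                         params = pasture_params()) {
  g <- land_cover$grid
  stopifnot(grids_aligned(g, lsu$grid), grids_aligned(g, koppen$grid),
            grids_aligned(g, ecoregion_excluded$grid))
  nontree <- !is.na(land_cover$data) &
    land_cover$data %in% params$nontree_lc_codes
  grazed <- !is.na(lsu$data) & lsu$data >= params$lsu_threshold
  kz <- koppen$data
  grp <- matrix(NA_character_, g$n_rows, g$n_cols)
  grp[!is.na(kz)] <- koppen_group(kz[!is.na(kz)])
  climate_ok <- matrix(forest_suitable_climate(grp, params$forest_climate_groups),
                       g$n_rows, g$n_cols)
  binary_mask(g, nontree & grazed & !ecoregion_excluded$data & climate_ok)
}

#' Rural-gardens mask
#'
#' Arable land in the "very small field size" category within a buffer
#' (default 500 m) of urban land cover. Urban cells themselves are never
#' gardens.
#'
#' @param land_cover,field_size aligned `categorical_layer`s.
#' @param urban_codes,arable_codes land-cover code sets.
#' @param very_small_code the very-small-fields category code.
#' @param buffer_m urban boundary radius in map units (default 500).
#' @return `binary_mask`.
#' @export
rural_gardens_mask <- function(land_cover, field_size,
                               urban_codes = 50L, arable_codes = 40L,
                               very_small_code = 1L, buffer_m = 500) {
  g <- land_cover$grid
  stopifnot(grids_aligned(g, field_size$grid))
  urban <- binary_mask(g, !is.na(land_cover$data) &
                            land_cover$data %in% urban_codes)
  near_urban <- if (any(urban$data)) binary_dilate(urban, buffer_m)$data
                else matrix(FALSE, g$n_rows, g$n_cols)
  arable <- !is.na(land_cover$data) & land_cover$data %in% arable_codes
  tiny <- !is.na(field_size$data) & field_size$data == very_small_code
  binary_mask(g, near_urban & arable & tiny & !urban$data)
}

#' Plantation-forest mask
#'
#' Membership of the forest-management classes treated as plantations:
#' replanted forest with rotation > 20 years, short-rotation woody
#' plantations, agroforestry and fruit plantations (shipped legend codes
#' 2-5).
#'
#' @param forest_mgmt `categorical_layer` of management codes.
#' @param plantation_mgmt_codes code set counted as plantation.
#' @return `binary_mask`.
#' @export
plantation_mask <- function(forest_mgmt, plantation_mgmt_codes = c(2L, 3L, 4L, 5L)) {
  stopifnot(length(plantation_mgmt_codes) >= 1)
  binary_mask(forest_mgmt$grid,
              !is.na(forest_mgmt$data) &
                forest_mgmt$data %in% plantation_mgmt_codes)
}

#' Expand wetland classes outward with a modal filter
#'
#' Growth-only expansion of a (coarse) wetland layer: cells already carrying
#' a wetland code are unchanged; nodata/non-wetland cells acquire the modal
#' wetland code of their window when any wetland code occurs there,
#' otherwise they keep their original value. Accounts for small-scale
#' differences in mapped water cover between the wetland product and the
#' finer land-cover grid.
#'
#' @param wetland `categorical_layer`.
#' @param radius_cells modal window half-width (default 2, i.e. a 5x5 window
#'   naming a ~5 km diameter at 1 km input resolution).
#' @param wetland_codes codes treated as wetland (default: every code
#'   present in the layer's legend).
#' @return `categorical_layer` with wetland area >= the input's.
#' @export
expand_wetlands <- function(wetland, radius_cells = 2,
                            wetland_codes = get_legend(wetland$legend_id)$codes) {
  stopifnot(inherits(wetland, "categorical_layer"))
  is_wet <- !is.na(wetland$data) & wetland$data %in% wetland_codes
  wet_only <- wetland$data
  wet_only[!is_wet] <- NA_integer_
  grown <- modal_filter(categorical_layer(wetland$grid, wet_only,
                                          wetland$legend_id),
                        radius_cells)$data
  out <- wetland$data
  take <- !is_wet & !is.na(grown)
  out[take] <- grown[take]
  categorical_layer(wetland$grid, out, wetland$legend_id)
}

#' Montane/lowland split
#'
#' A cell is montane iff the global mountain mask is set, or (when an
#' elevation threshold is supplied) its elevation reaches the threshold.
#'
#' @param mountain `binary_mask` (e.g. a K1-style mountain mask).
#' @param elevation `continuous_layer` in metres.
#' @param threshold_m optional elevation cutoff; `NULL` disables the
#'   elevation disjunct.
#' @return `binary_mask` of montane cells.
#' @export
mountain_split <- function(mountain, elevation, threshold_m = NULL) {
  g <- mountain$grid
  stopifnot(grids_aligned(g, elevation$grid))
  high <- if (is.null(threshold_m)) matrix(FALSE, g$n_rows, g$n_cols)
          else !is.na(elevation$data) & elevation$data >= threshold_m
  binary_mask(g, mountain$data | high)
}

#' Subtropics-and-tropics mask from biome codes
#'
#' Simple membership of a biome/ecoregion flag layer in a tropical code set.
#' Also reusable for any other code-membership mask (e.g. the grass/steppe
#' ecoregion exclusion).
#'
#' @param biome `categorical_layer`.
#' @param tropical_biome_codes code set; empty set gives an empty mask.
#' @return `binary_mask`.
#' @export
tropics_mask <- function(biome, tropical_biome_codes) {
  binary_mask(biome$grid,
              !is.na(biome$data) & biome$data %in% tropical_biome_codes)
}
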