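# File formats: layers as ESRI ASCII grids (plain-text single-band rasters
# readable by standard GIS software), records as CSV, polygons as GeoJSON
# FeatureCollections, legends/rulesets/configs as YAML, manifests as JSON.

#' Write a layer as an ESRI ASCII grid
#'
#' Single-band plain-text raster with the standard six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`).
#' Masks are written as 0/1, categorical layers as integer codes,
#' continuous layers as full-precision decimals. A small YAML sidecar
#' (`<path>.meta.yaml`) records the layer type and its legend or units so a
#' round trip restores the container exactly.
#'
#' @param layer a layer object.
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_layer_asc <- function(layer, path) {
  stopifnot(inherits(layer, "hm_layer"))
  g <- layer$grid
  d <- layer$data
  if (inherits(layer, "binary_mask")) d <- d * 1L
  d[is.na(d)] <- g$nodata
  header <- c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
              paste("xllcorner", format(g$origin_x, digits = 15)),
              paste("yllcorner",
                    format(g$origin_y - g$n_rows * g$cell_size, digits = 15)),
              paste("cellsize", format(g$cell_size, digits = 15)),
              paste("NODATA_value", g$nodata))
  body <- apply(d, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, body), path)
  meta <- list(type = class(layer)[1])
  if (inherits(layer, "categorical_layer")) meta$legend_id <- layer$legend_id
  if (inherits(layer, "continuous_layer")) meta$units <- layer$units
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_layer_asc()]
#'
#' Restores grid geometry, nodata and the layer container; the sidecar
#' metadata file determines the type, or pass `type` (plus `legend_id` /
#' `units`) to read a file produced elsewhere.
#'
#' @param path `.asc` file path.
#' @param type optional override: `"categorical_layer"`,
#'   `"continuous_layer"` or `"binary_mask"`.
#' @param legend_id,units metadata used when no sidecar exists.
#' @return A layer object.
#' @export
read_layer_asc <- function(path, type = NULL, legend_id = NULL, units = NULL) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("malformed ASCII grid header in ", path, ": missing ",
         paste(setdiff(need, keys), collapse = ", "))
  n_rows <- vals["nrows"]; n_cols <- vals["ncols"]; cs <- vals["cellsize"]
  g <- grid_spec(n_rows, n_cols, cell_size = cs,
                 origin_x = vals["xllcorner"],
                 origin_y = vals["yllcorner"] + n_rows * cs,
                 nodata = vals["nodata_value"])
  body <- lines[-(1:6)]
  if (length(body) != n_rows)
    stop("ASCII grid ", path, ": expected ", n_rows, " data rows, found ",
         length(body))
  d <- matrix(NA_real_, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    row <- scan(text = body[i], quiet = TRUE)
    if (length(row) != n_cols)
      stop("ASCII grid ", path, ", data row ", i, ": expected ", n_cols,
           " values, found ", length(row))
    d[i, ] <- row
  }
  d[d == g$nodata] <- NA
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  type <- type %||% meta$type %||% "continuous_layer"
  switch(type,
         categorical_layer = categorical_layer(
           g, d, legend_id %||% meta$legend_id %||% "unknown"),
         continuous_layer = continuous_layer(g, d, units %||% meta$units %||% ""),
         binary_mask = binary_mask(g, d > 0),
         stop("unknown layer type '", type, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write occurrence-record CSV files
#'
#' The documented column schema of [occurrence_records()]; unknown source
#' tags and malformed rows are rejected with their row number.
#'
#' @param path CSV path.
#' @param records an `occurrence_records` table.
#' @return `read_records_csv()`: an `occurrence_records` table.
#' @export
read_records_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "species_id", "x", "y", "observed_date",
            "coord_uncertainty_m", "source", "expected_code",
            "sampling_extent_m")
  if (!all(need %in% names(d)))
    stop("records CSV ", path, " lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(!d$source %in% c("gbif", "ebird", "predicts", "visual"))
  if (length(bad))
    stop("records CSV ", path, ", row ", bad[1], ": unknown source tag '",
         d$source[bad[1]], "'")
  occurrence_records(d$record_id, d$species_id, d$x, d$y, d$observed_date,
                     d$coord_uncertainty_m, d$source, d$expected_code,
                     d$sampling_extent_m)
}

#' @rdname read_records_csv
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records)[, c(
    "record_id", "species_id", "x", "y", "observed_date",
    "coord_uncertainty_m", "source", "expected_code", "sampling_extent_m")],
    path, row.names = FALSE)
  invisible(path)
}

#' Read and write validation polygons as GeoJSON
#'
#' FeatureCollections of single-ring Polygon features with `polygon_id` and
#' `expected_code` properties; coordinates are planar map coordinates.
#'
#' @param path GeoJSON file.
#' @param polygons data frame with `polygon_id`, `expected_code` and a
#'   `geometry` list-column of vertex matrices.
#' @return `read_polygons_geojson()`: such a data frame.
#' @export
read_polygons_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection: ", path)
  n <- length(doc$features)
  ids <- character(n); codes <- integer(n); geoms <- vector("list", n)
  for (i in seq_len(n)) {
    f <- doc$features[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon"))
      stop("feature ", i, " in ", path, " is not a Polygon")
    ring <- f$geometry$coordinates[[1]]
    geoms[[i]] <- do.call(rbind, lapply(ring, function(p)
      c(x = p[[1]], y = p[[2]])))
    ids[i] <- f$properties$polygon_id %||% sprintf("poly%05d", i)
    codes[i] <- as.integer(f$properties$expected_code %||% NA_integer_)
  }
  out <- data.frame(polygon_id = ids, expected_code = codes)
  out$geometry <- geoms
  out
}

#' @rdname read_polygons_geojson
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(seq_len(nrow(polygons)), function(i) {
    ring <- polygons$geometry[[i]]
    list(type = "Feature",
         properties = list(polygon_id = polygons$polygon_id[i],
                           expected_code = polygons$expected_code[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) as.numeric(ring[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Small stable content hash (FNV-1a over the serialized config) for run
# manifests; not cryptographic.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full pipeline on a configuration
#'
#' Stages execute in order: obtain the stack (from a synthetic world or from
#' `.asc` layer files), build derived masks if absent, classify to Level-2
#' and Level-1 maps, aggregate fractionally, and (optionally) validate
#' against generated or supplied records. All artifacts plus a JSON run
#' manifest (config hash, seed, per-stage cell counts, file list) are
#' written under `out_dir`; a rerun with the same config and inputs is
#' bit-identical.
#'
#' @param config list (or path to a YAML file) with entries: either
#'   `synthetic` (arguments for [world_params()]) or `layers` (named `.asc`
#'   paths); optional `ruleset` (YAML path), `aggregate_factor` (default
#'   10), `validate` (list: `n_records`, `mode`, plus [filter_params()]
#'   overrides), and `out_dir`.
#' @return List with `habitat_map`, `level1`, `fractional`, optional
#'   `validation`, and the `manifest`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(config_hash = fnv1a(config), stages = list(),
                   artifacts = character(0))

  world <- NULL
  stk <- stage("harmonize", {
    if (!is.null(config$synthetic)) {
      wp <- do.call(world_params, config$synthetic)
      world <- generate_world(wp)
      world$stack
    } else if (!is.null(config$layers)) {
      layers <- lapply(config$layers, read_layer_asc)
      layer_stack(layers)
    } else stop("config needs either 'synthetic' or 'layers'")
  })
  rs <- stage("ruleset", {
    if (!is.null(config$ruleset)) parse_ruleset(config$ruleset)
    else default_ruleset()
  })
  missing_layers <- setdiff(
    unique(unlist(lapply(rs$rules, function(r) predicate_layers(r$when)))),
    names(stk))
  if (length(missing_layers))
    stop("pipeline stage 'classify' aborted: ruleset references layer(s) ",
         "missing from the stack: ", paste(missing_layers, collapse = ", "))

  map <- stage("classify", classify(stk, rs))
  l1 <- stage("classify", level1_map(map))
  manifest$stages$classify <- list(
    cells = length(map$data), assigned = sum(!is.na(map$data)))

  factor <- config$aggregate_factor %||% 10
  fs <- stage("aggregate", fractional_aggregate(map, factor))
  manifest$stages$aggregate <- list(factor = factor,
                                    coarse_cells = length(fs$valid_fraction))

  art <- function(obj, name) {
    p <- file.path(out_dir, name)
    write_layer_asc(obj, p)
    manifest$artifacts <<- c(manifest$artifacts, name)
    p
  }
  art(map, "habitat_level2.asc")
  art(l1, "habitat_level1.asc")
  for (cd in fs$codes)
    art(fraction_layer(fs, cd), sprintf("fraction_%d.asc", cd))
  yaml::write_yaml(list(codes = as.integer(fs$codes), factor = fs$factor,
                        edge_truncated = fs$edge_truncated),
                   file.path(out_dir, "fractional_manifest.yaml"))

  validation <- NULL
  if (!is.null(config$validate)) {
    validation <- stage("validate", {
      v <- config$validate
      if (is.null(world))
        stop("validation against supplied records requires a synthetic world ",
             "in this configuration")
      gen <- generate_records(world, n = v$n_records %||% 1000)
      fp <- filter_params()
      flt <- filter_records(gen$records, gen$ranges, map$grid, fp)
      mm <- match_records(map, flt$records, fp,
                          mode = v$mode %||% "lenient")
      sum2 <- summarize_validation(list(synthetic = mm$pairs), level = 2,
                                   min_records = fp$min_records_per_class)
      sum1 <- summarize_validation(list(synthetic = mm$pairs), level = 1,
                                   min_records = fp$min_records_per_class)
      utils::write.csv(sum2$table, file.path(out_dir, "validation_level2.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(level1 = sum1[c("overall_accuracy", "mean_balanced_accuracy",
                             "sd_balanced_accuracy")],
             level2 = sum2[c("overall_accuracy", "mean_balanced_accuracy",
                             "sd_balanced_accuracy")],
             n_matched = nrow(mm$pairs), n_dropped = mm$n_dropped,
             rejections = as.list(flt$tally)),
        file.path(out_dir, "validation_summary.json"),
        auto_unbox = TRUE, digits = NA)
      manifest$stages$validate <- list(n_records = nrow(gen$records),
                                       n_matched = nrow(mm$pairs))
      list(level1 = sum1, level2 = sum2, rejections = flt$tally)
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(habitat_map = map, level1 = l1, fractional = fs,
                 validation = validation, manifest = manifest))
}

#' Areal class proportions of a habitat map
#'
#' Summarises a classified map: per-class cell counts and shares of the
#' mapped (non-nodata) area, at Level 2 or projected to Level 1.
#'
#' @param map a habitat `categorical_layer`.
#' @param level 1 or 2.
#' @return Data frame with `code`, `label`, `n_cells`, `proportion`.
#' @export
class_proportions <- function(map, level = 2) {
  codes <- as.vector(map$data)
  codes <- codes[!is.na(codes)]
  if (level == 1) codes <- level1_of(codes)
  tab <- table(codes)
  h <- habitat_legend()
  lab <- if (level == 2) h$label[match(as.integer(names(tab)), h$code)]
         else h$label[match(as.integer(names(tab)) * 100L, h$code)]
  data.frame(code = as.integer(names(tab)), label = lab,
             n_cells = as.integer(tab),
             proportion = as.numeric(tab) / length(codes), row.names = NULL)
}
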